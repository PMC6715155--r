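## Experiment-orchestration tests run on a reduced community (30 species)
## so that each paired simulation is cheap.

test_that("pairing integrity: zero intensities give identical arms", {
  cfg <- tiny_config(intensity_ranges = list(
    competition = c(0, 0), interference = c(0, 0),
    mortality_increase = c(0, 0), refuge = c(0, 0), recruitment = c(0, 0)))
  ens <- run_mixed_ensemble(n_webs = 3, n_draws = 2, config = cfg, seed = 5)
  expect_equal(nrow(ens), 6L)
  expect_equal(ens$diversity_ratio, rep(0, 6))
  expect_equal(ens$biomass_ratio, rep(0, 6))
  expect_equal(ens$production_ratio, rep(0, 6))
})

test_that("mixed ensemble draws intensities in range and reports link counts", {
  ens <- run_mixed_ensemble(n_webs = 4, n_draws = 3, config = tiny_config(),
                            seed = 6)
  expect_equal(nrow(ens), 12L)
  rg <- default_config()$intensity_ranges
  for (ty in c("competition", "interference", "mortality_increase",
               "refuge", "recruitment")) {
    v <- ens[[paste0("intensity_", ty)]]
    expect_true(all(v >= rg[[ty]][1] & v <= rg[[ty]][2]))
    expect_true(all(ens[[paste0("links_", ty)]] >= 0))
  }
  expect_true(all(ens$disconnected_plants >= 0))
  ## the ensemble is reproducible under its seed
  ens2 <- run_mixed_ensemble(n_webs = 4, n_draws = 3, config = tiny_config(),
                             seed = 6)
  expect_equal(ens, ens2)
})

test_that("single-NTI sweep reports per-intensity means and slopes", {
  sw <- run_single_nti_sweep(types = c("recruitment", "competition"),
                             n_webs = 3, n_draws = 2, grid_size = 3,
                             config = tiny_config(), seed = 7)
  expect_equal(nrow(sw$runs), 2 * 3 * 2 * 3)
  expect_setequal(unique(sw$runs$type), c("recruitment", "competition"))
  rg <- default_config()$intensity_ranges$recruitment
  grid <- unique(sw$runs$intensity[sw$runs$type == "recruitment"])
  expect_equal(sort(grid), seq(rg[1], rg[2], length.out = 3))
  expect_s3_class(sw$slopes$recruitment, "regression_fit")
  expect_true(all(c("diversity_ratio", "biomass_ratio", "production_ratio")
                  %in% names(sw$by_intensity)))
})

test_that("link-count setups scale the layer probabilities", {
  cfg <- tiny_config()
  tab <- run_link_count_ensemble(setups = list(c(100, 100), c(100, 50)),
                                 n_webs = 2, n_draws = 2, config = cfg,
                                 seed = 8)
  expect_equal(nrow(tab), 8L)
  expect_setequal(unique(tab$setup), c("100+/100-", "100+/50-"))
  expect_true(all(tab$links_positive >= 0))
  ## halving the negative-side budget halves the expected negative links;
  ## verify via the drawn layers over many repetitions on one fixed web
  set.seed(9)
  web <- generate_niche_web(cfg$S, cfg$connectance, cfg$n_plants)
  traits <- assign_traits(web, cfg)
  p_full <- cfg$p_nti[["mortality_increase"]] / 4       # 4 negative types
  mean_full <- mean(replicate(200, draw_nti_layer(
    web, traits, "mortality_increase", p_full)$n_links))
  mean_half <- mean(replicate(200, draw_nti_layer(
    web, traits, "mortality_increase", p_full / 2)$n_links))
  expect_lt(abs(mean_half / mean_full - 0.5), 0.2)
})

test_that("sensitivity suite reports slopes per parameter setting", {
  sens <- run_sensitivity_suite(
    settings = list(default = list(),
                    a0_low = list(a0 = 10, a0_sesscons = 10,
                                  a0_sessres = 10, h0 = 0.1)),
    n_webs = 4, n_draws = 2, config = tiny_config(), seed = 10)
  expect_equal(nrow(sens$slopes), 2L)
  expect_setequal(sens$slopes$setting, c("default", "a0_low"))
  expect_true(all(is.finite(sens$slopes$slope_with)))
  expect_true(all(is.finite(sens$slopes$ancova_p)))
  expect_equal(nrow(sens$ensembles$default), 8L)
})

test_that("intensity calibration handles the trivial and unreachable cases", {
  cal0 <- calibrate_intensity("recruitment", 0, tiny_config())
  expect_equal(cal0$intensity, 0)
  expect_true(cal0$converged)
  ## a large target under a tiny intensity bound is reported, not forced
  cal <- calibrate_intensity("interference", -0.45, tiny_config(),
                             n_webs = 2, n_draws = 1,
                             bounds = c(0, 1e-4), seed = 11)
  expect_false(cal$converged)
  expect_lt(abs(cal$achieved), 0.45)
  expect_equal(cal$intensity, 1e-4)
})
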