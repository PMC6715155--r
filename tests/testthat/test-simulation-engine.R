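cfg <- default_config()

test_that("initial biomass draws respect the range and pairing contract", {
  set.seed(91)
  B <- draw_initial_biomasses(500)
  expect_true(all(B >= 0.05 & B <= 1))
  set.seed(17)
  B1 <- draw_initial_biomasses(100)
  set.seed(17)
  B2 <- draw_initial_biomasses(100)
  expect_identical(B1, B2)
})

test_that("an isolated plant settles at the logistic-with-mortality equilibrium", {
  par <- plant_params()
  res <- simulate_community(par, B0 = 0.5, config = cfg)
  Bstar <- 1 * (1 - 0.0138 / 1)
  expect_equal(res$B_final, Bstar, tolerance = 1e-4)
  expect_true(res$alive)
  ## at equilibrium the production term balances the mortality outflow
  met <- compute_metrics(res, par, TL = 1)
  expect_equal(met$total_production, 0.0138 * Bstar, tolerance = 1e-3)
  expect_equal(met$diversity, 1L)
})

test_that("biomass below the threshold is immediately extinct and stays so", {
  par <- plant_params()
  res <- simulate_community(par, B0 = 1e-7, config = cfg)
  expect_equal(res$B_final, 0)
  expect_false(res$alive)
  expect_equal(res$extinction_times, 0)
  expect_equal(compute_metrics(res, par, TL = 1)$diversity, 0L)
})

test_that("trajectories stay nonnegative and extinct species stay at zero", {
  set.seed(101)
  web <- generate_niche_web(30, 0.08, 6)
  traits <- assign_traits(web, tiny_config())
  par <- build_model_params(web, traits, cfg)
  B0 <- draw_initial_biomasses(30)
  times <- c(1, 5, 20, 100, 500, 2000, 5000)
  res <- simulate_community(par, B0 = B0, config = cfg, sample_times = times)
  expect_true(all(res$trajectory >= 0))
  expect_equal(dim(res$trajectory), c(7L, 30L))
  ## once a species drops out it never reappears at a later sample
  for (i in seq_len(30)) {
    b <- res$trajectory[, i]
    if (any(b == 0)) expect_true(all(b[which(b == 0)[1]:7] == 0))
  }
  expect_true(all(res$B_final[res$alive] >= cfg$ext_threshold))
  expect_true(all(res$B_final[!res$alive] == 0))
})

test_that("paired runs with identical seeds are bit-reproducible", {
  set.seed(111)
  web <- generate_niche_web(30, 0.08, 6)
  traits <- assign_traits(web, tiny_config())
  par <- build_model_params(web, traits, cfg)
  B0 <- draw_initial_biomasses(30)
  r1 <- simulate_community(par, B0 = B0, config = cfg)
  r2 <- simulate_community(par, B0 = B0, config = cfg)
  expect_identical(r1$B_final, r2$B_final)
  expect_identical(r1$alive, r2$alive)
})

test_that("solver tolerances are tight enough that results are insensitive", {
  set.seed(121)
  web <- generate_niche_web(30, 0.08, 6)
  traits <- assign_traits(web, tiny_config())
  par <- build_model_params(web, traits, cfg)
  B0 <- draw_initial_biomasses(30)
  r1 <- simulate_community(par, B0 = B0, config = cfg)
  r2 <- simulate_community(par, B0 = B0, config = cfg,
                           rtol = cfg$rtol / 10, atol = cfg$atol / 10)
  expect_equal(r1$diversity, r2$diversity)
  expect_lt(abs(sum(r1$B_final) - sum(r2$B_final)) / sum(r2$B_final), 1e-3)
})

test_that("plants persist in trophic-only runs at default parameters", {
  set.seed(131)
  for (k in 1:20) {
    web <- generate_niche_web(100, 0.06, 20)
    traits <- assign_traits(web, cfg)
    par <- build_model_params(web, traits, cfg)
    res <- simulate_community(par, B0 = draw_initial_biomasses(100),
                              config = cfg)
    expect_equal(sum(res$alive & web$is_plant), 20L)
    ## and a nontrivial part of the community survives
    expect_gt(res$diversity, 20L)
  }
})

test_that("community metrics partition by trophic-level class", {
  set.seed(141)
  web <- generate_niche_web(30, 0.08, 6)
  traits <- assign_traits(web, tiny_config())
  par <- build_model_params(web, traits, cfg)
  res <- simulate_community(par, B0 = draw_initial_biomasses(30),
                            config = cfg)
  met <- compute_metrics(res, par, TL = traits$TL)
  expect_equal(sum(met$per_tl$diversity), met$diversity)
  expect_equal(sum(met$per_tl$biomass), met$total_biomass)
  expect_equal(sum(met$per_tl$production), met$total_production)
  expect_gte(met$total_biomass, 0)
  ## all-plant special case: a single class carries the totals
  par1 <- plant_params()
  res1 <- simulate_community(par1, B0 = 0.5, config = cfg)
  met1 <- compute_metrics(res1, par1, TL = 1)
  expect_equal(met1$per_tl$biomass[1], met1$total_biomass)
  expect_equal(met1$per_tl$diversity[2:3], c(0L, 0L))
})

test_that("normalized ratios compare paired metrics", {
  expect_equal(normalized_ratio(110, 100), 0.10)
  expect_equal(normalized_ratio(90, 100), -0.10)
  expect_equal(normalized_ratio(100, 100), 0)
  expect_true(is.na(normalized_ratio(5, 0)))
  expect_equal(normalized_ratio(c(110, 90), c(100, 100)), c(0.1, -0.1))
})

test_that("the compiled integrator matches an independent ODE solver", {
  ## plant-herbivore pair, horizon short of any extinction
  adj <- matrix(FALSE, 2, 2)
  adj[2, 1] <- TRUE
  web <- make_web(adj)
  traits <- make_traits(c(TRUE, FALSE), compute_trophic_levels(web))
  par <- build_model_params(web, traits, cfg)
  nti <- empty_nti_state(par)
  B0 <- c(0.6, 0.4)
  res <- simulate_community(par, nti, B0, cfg, t_max = 200)
  ref <- deSolve::ode(y = B0, times = c(0, 200),
                      func = function(t, y, p) list(rhs(par, nti, y)),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  expect_true(all(res$alive))
  expect_equal(res$B_final, unname(ref[2, 2:3]), tolerance = 1e-6)
})
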