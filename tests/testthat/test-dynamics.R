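cfg <- default_config()

test_that("allometric parameter assembly matches the scalings", {
  ## isolated plant of unit mass
  p <- plant_params()
  expect_equal(p$r, 1)
  expect_equal(p$d, 0.1 * 0.138)
  expect_equal(p$x, 0)
  expect_equal(p$K, 1)

  ## mobile herbivore (m = 50) on a mobile plant (m = 1)
  web <- chain_web()
  traits <- make_traits(rep(FALSE, 3), compute_trophic_levels(web))
  par <- build_model_params(web, traits, cfg)
  expect_equal(par$m, c(1, 50, 2500))
  expect_equal(par$a_base[2, 1], 50 * 50^0.45)
  expect_equal(par$h[2, 1], 0.3 * 50^-0.48)
  expect_equal(par$eps[2, 1], 0.45)
  expect_equal(par$eps[3, 2], 0.85)
  expect_equal(par$x[2], 0.314 * 50^-0.25)
  expect_equal(par$d[3], 0.1 * 0.314 * 2500^-0.25)

  ## sessile cases of the capture coefficient
  tr2 <- make_traits(c(TRUE, TRUE, FALSE), compute_trophic_levels(web))
  par2 <- build_model_params(web, tr2, cfg)
  expect_equal(par2$a_base[2, 1], 50 * 1^0.15)        # sessile consumer
  expect_equal(par2$a_base[3, 2], 50 * 2500^0.45)     # sessile resource

  ## relative consumption is one over the structural diet size
  adj <- matrix(FALSE, 5, 5)
  adj[5, 1:4] <- TRUE
  web4 <- make_web(adj)
  par4 <- build_model_params(web4,
                             make_traits(rep(FALSE, 5),
                                         compute_trophic_levels(web4)), cfg)
  expect_equal(par4$w[5], 0.25)
})

test_that("refuge provisioning scales capture coefficients down", {
  web <- chain_web()
  traits <- make_traits(c(TRUE, FALSE, FALSE), compute_trophic_levels(web))
  par <- build_model_params(web, traits, cfg)
  nti <- empty_nti_state(par)
  B <- c(1, 0.5, 0.2)

  ## no refuge links: unchanged
  expect_equal(effective_attack(par, nti, B), par$a_base)

  ## plant shelters the herbivore from the predator: a[3, 2] shrinks by
  ## 1/(1 + 1.75 * 1)
  nti$phi[1, 2] <- 1
  nti$r0_refuge <- 1.75
  a <- effective_attack(par, nti, B)
  expect_equal(a[3, 2], par$a_base[3, 2] / 2.75)
  expect_equal(a[2, 1], par$a_base[2, 1])

  ## capture rate vanishes as facilitator biomass grows
  expect_lt(effective_attack(par, nti, c(1e6, 0.5, 0.2))[3, 2] /
              par$a_base[3, 2], 1e-5)
})

test_that("mortality and growth modifiers follow their linear forms", {
  par <- plant_params()
  web <- chain_web()
  traits <- make_traits(rep(FALSE, 3), compute_trophic_levels(web))
  par3 <- build_model_params(web, traits, cfg)
  nti <- empty_nti_state(par3)
  B <- c(1, 1, 1)
  expect_equal(effective_mortality(par3, nti, B), par3$d)
  expect_equal(effective_growth(par3, nti, B), par3$r)

  ## one negative effector of biomass 1 at n0 = 3 quadruples mortality
  nti$n_mat[1, 3] <- 1
  nti$n0 <- 3
  expect_equal(effective_mortality(par3, nti, B)[3], par3$d[3] * 4)

  ## one positive effector of biomass 1 at p0 = 20 divides by 21
  nti2 <- empty_nti_state(par3)
  nti2$p_mat[1, 3] <- 1
  nti2$p0 <- 20
  expect_equal(effective_mortality(par3, nti2, B)[3], par3$d[3] / 21)

  ## one recruitment facilitator of biomass 1 at e0 = 1.8 multiplies plant
  ## growth by 2.8; consumers keep r = 0
  nti3 <- empty_nti_state(par3)
  nti3$eta[2, 1] <- 1
  nti3$e0 <- 1.8
  rn <- effective_growth(par3, nti3, B)
  expect_equal(rn[1], par3$r[1] * 2.8)
  expect_equal(rn[2:3], c(0, 0))
})

test_that("single-prey functional response reduces to the closed form", {
  web <- chain_web()
  traits <- make_traits(rep(FALSE, 3), compute_trophic_levels(web))
  par <- build_model_params(web, traits, cfg)
  par$i0_intra <- 0   # isolate the Holling core
  nti <- empty_nti_state(par)
  nti$i0_intra <- 0
  B <- c(0.7, 0.3, 0.1)
  Fm <- functional_response(par, nti, B)
  a <- par$a_base[2, 1]; h <- par$h[2, 1]
  expect_equal(Fm[2, 1],
               a * 0.7^1.5 / (50 * (1 + a * h * 0.7^1.5)))
  expect_equal(Fm[1, ], rep(0, 3))        # plants never feed
  expect_equal(Fm[2, c(2, 3)], c(0, 0))   # zero off the adjacency
  ## all-prey-extinct consumer has zero feeding everywhere
  expect_equal(functional_response(par, nti, c(0, 0.3, 0.1))[2, ], rep(0, 3))
})

test_that("interference strictly decreases the feeding of competing predators", {
  ## two equal-mass predators sharing one prey
  adj <- matrix(FALSE, 3, 3)
  adj[2, 1] <- TRUE
  adj[3, 1] <- TRUE
  web <- make_web(adj)
  traits <- make_traits(rep(FALSE, 3), compute_trophic_levels(web))
  par <- build_model_params(web, traits, cfg)
  nti <- empty_nti_state(par)
  nti$delta[2, 3] <- nti$delta[3, 2] <- 1   # delta = 1 at equal masses
  nti$i0 <- 3
  B <- c(0.8, 0.4, 0.4)
  F1 <- functional_response(par, nti, B)[2, 1]
  F2 <- functional_response(par, nti, c(0.8, 0.4, 0.8))[2, 1]
  expect_lt(F2, F1)
  ## and the response is non-increasing in the interference intensity
  nti_weak <- nti; nti_weak$i0 <- 0.5
  expect_gt(functional_response(par, nti_weak, B)[2, 1], F1)
})

test_that("competition factor reduces growth only under positive net growth", {
  web <- chain_web()
  traits <- make_traits(rep(TRUE, 3), compute_trophic_levels(web))
  par <- build_model_params(web, traits, cfg)
  nti <- empty_nti_state(par)
  ## competitor of mass 50 (gamma = 50^(2/3)) and biomass 1 at c0 = 0.012
  nti$gamma[1, 2] <- 50^(2 / 3)
  nti$c0 <- 0.012
  B <- c(0.5, 1, 0.1)
  g_pos <- competition_factor(par, nti, B, net_growth = c(1, 1, 1))
  expect_equal(g_pos[1], 1 - 0.012 * 50^(2 / 3) * 1)
  expect_equal(g_pos[2:3], c(1, 1))
  ## negative net growth switches competition off
  expect_equal(competition_factor(par, nti, B, net_growth = c(-1, 1, 1))[1], 1)
  ## no competition links leaves g = 1 everywhere
  expect_equal(competition_factor(par, empty_nti_state(par), B, c(1, 1, 1)),
               rep(1, 3))
  ## the factor is clamped at zero by default, and unbounded when disabled
  nti$c0 <- 1
  expect_equal(competition_factor(par, nti, B, c(1, 1, 1))[1], 0)
  par$clamp_g <- FALSE
  expect_equal(competition_factor(par, nti, B, c(1, 1, 1))[1],
               1 - 50^(2 / 3))
})

test_that("zero-intensity dynamics reduce to the plain trophic model", {
  set.seed(61)
  web <- generate_niche_web(40, 0.08, 8)
  traits <- assign_traits(web, default_config(S = 40L, n_sessile = 13L))
  par <- build_model_params(web, traits, cfg)
  nti <- empty_nti_state(par)
  for (k in 1:10) {
    B <- stats::runif(40, 0, 1.5)
    B[sample(40, 4)] <- 0
    expect_equal(rhs(par, nti, B), trophic_rhs_oracle(par, B),
                 tolerance = 1e-12)
  }
})

test_that("compiled and reference right-hand sides agree with full NTI state", {
  set.seed(71)
  web <- generate_niche_web(60, 0.07, 12)
  traits <- assign_traits(web, default_config(S = 60L, n_sessile = 20L))
  par <- build_model_params(web, traits, cfg)
  mx <- draw_multiplex(web, traits,
                       intensities = c(competition = 0.012, interference = 3,
                                       mortality_increase = 3,
                                       mortality_decrease = 20,
                                       refuge = 1.75, recruitment = 1.8))
  nti <- build_nti_state(mx, cfg)
  model <- build_sim_model(par, nti)
  for (k in 1:10) {
    B <- stats::runif(60, 0, 1.2)
    B[sample(60, 5)] <- 0
    expect_equal(rhs(par, nti, B), multiwebsim:::rhs_compiled(model, B), tolerance = 1e-10)
  }
})

test_that("zero biomass is absorbing", {
  set.seed(81)
  web <- generate_niche_web(30, 0.1, 6)
  traits <- assign_traits(web, tiny_config())
  par <- build_model_params(web, traits, cfg)
  nti <- empty_nti_state(par)
  B <- stats::runif(30)
  B[c(3, 10, 25)] <- 0
  dB <- rhs(par, nti, B)
  expect_equal(dB[c(3, 10, 25)], c(0, 0, 0))
})
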