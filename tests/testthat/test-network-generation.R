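test_that("generated webs satisfy the structural constraints", {
  set.seed(11)
  webs <- replicate(40, generate_niche_web(100, 0.06, 20), simplify = FALSE)
  for (web in webs) {
    expect_equal(sum(web$is_plant), 20L)
    nonself <- web$adjacency
    diag(nonself) <- FALSE
    ## every consumer keeps a non-self resource, nobody is isolated
    expect_true(all(web$is_plant | rowSums(nonself) > 0L))
    expect_true(all(rowSums(nonself) + colSums(nonself) > 0L))
    ## acyclic apart from self-loops
    expect_true(multiwebsim:::is_acyclic(nonself))
  }
  ## realized connectance concentrates near the target
  conn <- vapply(webs, function(w) w$n_links / w$S^2, numeric(1))
  expect_gt(mean(conn), 0.06 * 0.90)
  expect_lt(mean(conn), 0.06 * 1.10)
})

test_that("the minimal two-species web is a single consumer-plant link", {
  set.seed(2)
  web <- generate_niche_web(2, 0.2, 1)
  expect_equal(sum(web$is_plant), 1L)
  nonself <- web$adjacency
  diag(nonself) <- FALSE
  expect_equal(sum(nonself), 1L)
  expect_true(nonself[which(!web$is_plant), which(web$is_plant)])
})

test_that("web generation is reproducible under a fixed seed", {
  set.seed(99)
  w1 <- generate_niche_web(60, 0.07, 12)
  set.seed(99)
  w2 <- generate_niche_web(60, 0.07, 12)
  expect_identical(w1$adjacency, w2$adjacency)
  expect_identical(w1$niche, w2$niche)
})

test_that("prey-averaged trophic levels follow the recursive definition", {
  ## plant alone
  expect_equal(compute_trophic_levels(plant_web()), 1)
  ## consumer eating two plants sits exactly one level up
  adj <- matrix(FALSE, 3, 3)
  adj[3, 1:2] <- TRUE
  expect_equal(compute_trophic_levels(make_web(adj)), c(1, 1, 2))
  ## omnivore eating one plant and one herbivore averages its resources
  adj <- matrix(FALSE, 4, 4)
  adj[2, 1] <- TRUE             # herbivore
  adj[3, 1] <- TRUE             # second herbivore... no: plant 1 only
  adj[4, c(1, 2)] <- TRUE       # omnivore: plant (TL 1) + herbivore (TL 2)
  expect_equal(compute_trophic_levels(make_web(adj)), c(1, 2, 2, 2.5))
  ## cannibalistic self-loops are excluded from the average
  adj <- matrix(FALSE, 2, 2)
  adj[2, 1] <- TRUE
  adj[2, 2] <- TRUE
  expect_equal(compute_trophic_levels(make_web(adj)), c(1, 2))
  ## a consumer with only itself as resource is rejected
  adj <- matrix(FALSE, 2, 2)
  adj[2, 2] <- TRUE
  web <- make_web(adj)
  web$is_plant <- c(TRUE, FALSE)
  expect_error(compute_trophic_levels(web), "non-self resource")
})

test_that("body masses scale geometrically with trophic level", {
  expect_equal(assign_body_masses(1, 50), 1)
  expect_equal(assign_body_masses(2, 50), 50)
  expect_equal(assign_body_masses(2.5, 50), 50^1.5)
  expect_equal(assign_body_masses(c(1, 3), 25), c(1, 625))
  ## expo = 1 collapses all masses to 1 regardless of level
  expect_equal(assign_body_masses(c(1, 2.7, 4.2), 1), c(1, 1, 1))
})

test_that("mobility draws hit the exact sessile count", {
  set.seed(21)
  web <- generate_niche_web(100, 0.06, 20)
  for (k in 1:5) {
    s <- assign_mobility(web, 33, 0.8, 0.2)
    expect_equal(sum(s), 33L)
  }
  ## deterministic corner: all plants sessile, all consumers mobile
  s <- assign_mobility(web, sum(web$is_plant), 1, 0)
  expect_identical(s, web$is_plant)
  ## expected pre-rejection sessile count is 20*0.8 + 80*0.2 = 32
  set.seed(5)
  draws <- replicate(4000, {
    p <- ifelse(web$is_plant, 0.8, 0.2)
    sum(stats::runif(100) < p)
  })
  expect_lt(abs(mean(draws) - 32), 0.25)
  ## impossible target fails with a diagnostic
  expect_error(assign_mobility(web, 50, 1, 0, max_attempts = 10),
               "failed")
})

test_that("surviving plants must keep surviving consumers", {
  web <- chain_web()
  ## all alive: the plant keeps its herbivore
  expect_true(validate_connected_plants(web, rep(TRUE, 3)))
  ## herbivore extinct, plant alive: disconnected
  expect_false(validate_connected_plants(web, c(TRUE, FALSE, TRUE)))
  ## plant and herbivore both extinct: only surviving plants are checked
  expect_true(validate_connected_plants(web, c(FALSE, FALSE, TRUE)))
})
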