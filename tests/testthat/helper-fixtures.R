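## Hand-built fixtures and independent reference implementations used as
## oracles across the test files.

## Construct a trophic_web from an explicit adjacency matrix
## (adj[i, j] = TRUE iff consumer i eats resource j).
make_web <- function(adj, niche = NULL) {
  S <- nrow(adj)
  nonself <- adj
  diag(nonself) <- FALSE
  structure(list(S = S, adjacency = adj,
                 is_plant = rowSums(adj) == 0L,
                 niche = if (is.null(niche)) seq_len(S) / (S + 1) else niche,
                 n_links = sum(adj)),
            class = "trophic_web")
}

make_traits <- function(is_sessile, TL, expo = 50) {
  structure(list(is_sessile = is_sessile, TL = TL, mass = expo^(TL - 1)),
            class = "species_traits")
}

## A linear plant -> herbivore -> predator chain.
chain_web <- function() {
  adj <- matrix(FALSE, 3, 3)
  adj[2, 1] <- TRUE    # herbivore eats plant
  adj[3, 2] <- TRUE    # predator eats herbivore
  make_web(adj)
}

## One isolated plant (smallest system with nontrivial dynamics).
plant_web <- function() make_web(matrix(FALSE, 1, 1))

plant_params <- function(config = default_config()) {
  build_model_params(plant_web(), make_traits(TRUE, 1), config)
}

## Small community used for integration tests: 3 plants, 2 herbivores,
## 1 top predator.
small_web <- function() {
  adj <- matrix(FALSE, 6, 6)
  adj[4, 1:2] <- TRUE          # herbivore 1 eats plants 1-2
  adj[5, 2:3] <- TRUE          # herbivore 2 eats plants 2-3
  adj[6, 4:5] <- TRUE          # predator eats both herbivores
  make_web(adj)
}

small_traits <- function() {
  make_traits(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
              compute_trophic_levels(small_web()))
}

## Independent scalar implementation of the plain trophic model (no NTI
## terms except intraspecific interference), written with explicit loops:
## the oracle for the vectorised/compiled right-hand side.
trophic_rhs_oracle <- function(params, B) {
  S <- params$S
  q <- params$q
  Fm <- matrix(0, S, S)
  for (i in seq_len(S)) {
    hsum <- 0
    for (k in seq_len(S)) {
      if (params$adjacency[i, k]) {
        hsum <- hsum + params$w[i] * params$a_base[i, k] * params$h[i, k] *
          max(B[k], 0)^(1 + q)
      }
    }
    for (j in seq_len(S)) {
      if (params$adjacency[i, j]) {
        Fm[i, j] <- params$w[i] * params$a_base[i, j] * max(B[j], 0)^(1 + q) /
          (params$m[i] * (1 + params$i0_intra * max(B[i], 0) + hsum))
      }
    }
  }
  dB <- numeric(S)
  for (i in seq_len(S)) {
    gains <- sum(params$eps[i, ] * Fm[i, ])
    G <- 1 - B[i] / params$K[i]
    loss <- 0
    for (k in seq_len(S)) loss <- loss + B[k] * Fm[k, i]
    dB[i] <- (params$r[i] * G + gains - params$x[i]) * B[i] - loss -
      params$d[i] * B[i]
    if (B[i] <= 0) dB[i] <- 0
  }
  dB
}

## Closed-form simple linear regression (normal equations), the oracle for
## fit_linear()/ancova_slopes().
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sigma2 <- sum(resid^2) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tval <- slope / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(slope = slope, intercept = intercept, slope_stderr = se, p_value = p)
}

## Reduced-size study configuration for experiment smoke tests.
tiny_config <- function(...) {
  default_config(S = 30L, connectance = 0.08, n_plants = 8L, n_sessile = 10L,
                 ...)
}
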