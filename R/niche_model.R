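#' Generate a niche-model trophic web
#'
#' Samples food-web topologies from the Williams-Martinez niche model and
#' rejection-resamples until the web satisfies the structural constraints
#' used throughout the package: an exact number of basal (plant) species, no
#' directed cycle of length two or more (cannibalistic self-loops are
#' allowed), no isolated species, and every consumer with at least one
#' non-self resource.
#'
#' Each species receives a niche value \eqn{n_i \sim U(0,1)}; its feeding
#' range is \eqn{r_i = n_i x_i} with \eqn{x_i \sim Beta(1, 1/(2C) - 1)} so
#' that the expected connectance is `C`, and the range centre is uniform on
#' \eqn{[r_i/2, n_i]}.  Species `i` eats every species whose niche value
#' falls inside its feeding interval.  The species with the smallest niche
#' value is forced basal.
#'
#' @param S number of species.
#' @param C target connectance (directed links / S^2).
#' @param n_plants exact number of basal species required.
#' @param max_attempts rejection-sampling cap; a web failing the constraints
#'   this many times aborts with a diagnostic.
#' @return an object of class `"trophic_web"`: a list with elements `S`,
#'   `adjacency` (S x S logical, `[i, j]` means consumer `i` eats resource
#'   `j`), `is_plant`, `niche`, and `n_links`.
#' @examples
#' set.seed(1)
#' web <- generate_niche_web(40, 0.08, n_plants = 8)
#' web
#' @export
generate_niche_web <- function(S, C, n_plants,
                               max_attempts = default_config()$max_attempts) {
  stopifnot(S >= 2, C > 0, C < 1, n_plants >= 1, n_plants < S)
  beta <- 1 / (2 * C) - 1
  if (beta <= 0) stop("connectance must be < 0.5 for the niche model")
  for (attempt in seq_len(max_attempts)) {
    n <- stats::runif(S)
    x <- stats::rbeta(S, 1, beta)
    r <- n * x
    r[which.min(n)] <- 0            # smallest-niche species is always basal
    centre <- stats::runif(S, r / 2, n)
    lo <- centre - r / 2
    hi <- centre + r / 2
    ## adjacency[i, j]: j's niche value inside i's feeding interval
    adjacency <- outer(lo, n, "<=") & outer(hi, n, ">=")
    adjacency[r == 0, ] <- FALSE
    diet_sizes <- rowSums(adjacency)
    nonself <- adjacency
    diag(nonself) <- FALSE
    is_plant <- diet_sizes == 0L
    if (sum(is_plant) != n_plants) next
    ## consumers whose only resource is themselves are malformed
    if (any(!is_plant & rowSums(nonself) == 0L)) next
    ## no isolated species (self-loops do not connect)
    if (any(rowSums(nonself) + colSums(nonself) == 0L)) next
    if (!is_acyclic(nonself)) next
    web <- structure(
      list(S = S, adjacency = adjacency, is_plant = is_plant,
           niche = n, n_links = sum(adjacency)),
      class = "trophic_web")
    attr(web, "attempts") <- attempt
    return(web)
  }
  stop("niche-model rejection sampling failed after ", max_attempts,
       " attempts (S = ", S, ", C = ", C, ", n_plants = ", n_plants, ")")
}

## Kahn's algorithm on the self-loop-free adjacency (edges consumer -> resource)
is_acyclic <- function(adj) {
  indeg <- colSums(adj)              # number of consumers per species
  queue <- which(indeg == 0L)
  removed <- 0L
  active <- adj
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    removed <- removed + 1L
    res <- which(active[v, ])
    if (length(res) > 0L) {
      active[v, ] <- FALSE
      indeg[res] <- indeg[res] - 1L
      queue <- c(queue, res[indeg[res] == 0L])
    }
  }
  removed == ncol(adj)
}

#' Prey-averaged trophic levels
#'
#' Computes the prey-averaged trophic level: 1 for plants, and one plus the
#' mean trophic level of a consumer's resources otherwise.  Cannibalistic
#' self-loops are excluded from the average (including them would make the
#' level undefined).  On an acyclic web the defining linear system
#' \eqn{(I - W)\,TL = 1}, with `W` the row-normalised self-loop-free
#' adjacency, has a unique solution.
#'
#' @param web a `"trophic_web"`.
#' @return numeric vector of trophic levels (>= 1; == 1 exactly for plants).
#' @export
compute_trophic_levels <- function(web) {
  adj <- web$adjacency
  diag(adj) <- FALSE
  nres <- rowSums(adj)
  if (any(!web$is_plant & nres == 0L)) {
    stop("consumer without a non-self resource: trophic level undefined")
  }
  W <- adj / pmax(nres, 1L)
  W[nres == 0L, ] <- 0
  TL <- solve(diag(web$S) - W, rep(1, web$S))
  as.numeric(TL)
}

#' Allometric body masses from trophic level
#'
#' Body mass grows geometrically with trophic level,
#' \eqn{m_i = expo^{(TL_i - 1)}}, so plants have mass 1 and each trophic
#' level multiplies mass by `expo`.
#'
#' @param TL trophic-level vector (>= 1).
#' @param expo mass ratio per trophic level (default 50).
#' @return numeric mass vector.
#' @export
assign_body_masses <- function(TL, expo = default_config()$expo) {
  stopifnot(all(TL >= 1 - 1e-9), expo > 0)
  expo^(TL - 1)
}

#' Draw mobility traits with an exact sessile-species count
#'
#' Each species is independently sessile with probability `p_sessile_plant`
#' (plants) or `p_sessile_other` (consumers); the whole draw is repeated
#' until the web contains exactly `n_sessile` sessile species.  Plants are
#' given the higher probability, so space-dependent mechanisms (competition
#' for space, refuge provisioning) predominantly involve plants.
#'
#' @param web a `"trophic_web"`.
#' @param n_sessile exact sessile count to enforce.
#' @param p_sessile_plant,p_sessile_other per-species sessile probabilities.
#' @param max_attempts cap on redraws.
#' @return logical vector `is_sessile`.
#' @export
assign_mobility <- function(web, n_sessile = default_config()$n_sessile,
                            p_sessile_plant = default_config()$p_sessile_plant,
                            p_sessile_other = default_config()$p_sessile_other,
                            max_attempts = default_config()$max_attempts) {
  stopifnot(n_sessile <= web$S, n_sessile >= 0)
  p <- ifelse(web$is_plant, p_sessile_plant, p_sessile_other)
  for (attempt in seq_len(max_attempts)) {
    is_sessile <- stats::runif(web$S) < p
    if (sum(is_sessile) == n_sessile) return(is_sessile)
  }
  stop("mobility assignment failed to hit ", n_sessile,
       " sessile species after ", max_attempts, " attempts")
}

#' Assemble species traits for a web
#'
#' Convenience wrapper drawing mobility and computing trophic levels and
#' allometric body masses in one call.
#'
#' @param web a `"trophic_web"`.
#' @param config an `"mws_config"` (controls `n_sessile`, sessile
#'   probabilities and `expo`).
#' @return an object of class `"species_traits"`: list with `is_sessile`,
#'   `TL` and `mass`.
#' @export
assign_traits <- function(web, config = default_config()) {
  TL <- compute_trophic_levels(web)
  structure(
    list(is_sessile = assign_mobility(web, config$n_sessile,
                                      config$p_sessile_plant,
                                      config$p_sessile_other,
                                      config$max_attempts),
         TL = TL,
         mass = assign_body_masses(TL, config$expo)),
    class = "species_traits")
}

#' Check that every surviving plant keeps a surviving consumer
#'
#' Communities in which a surviving plant has no surviving consumer at the
#' end of the dynamics ("disconnected plants") are discarded by the ensemble
#' experiments; this predicate implements that filter.  Plants that are
#' themselves extinct are not checked.
#'
#' @param web a `"trophic_web"`.
#' @param alive logical survival vector of length `S`.
#' @return `TRUE` iff no surviving plant is left without a surviving consumer.
#' @export
validate_connected_plants <- function(web, alive) {
  stopifnot(length(alive) == web$S)
  plants <- which(web$is_plant & alive)
  for (i in plants) {
    if (!any(alive & web$adjacency[, i])) return(FALSE)
  }
  TRUE
}

#' @export
print.trophic_web <- function(x, ...) {
  cat(sprintf("niche-model trophic web: %d species (%d plants), %d links (connectance %.4f)\n",
              x$S, sum(x$is_plant), x$n_links, x$n_links / x$S^2))
  invisible(x)
}

#' @export
print.species_traits <- function(x, ...) {
  cat(sprintf("species traits: %d sessile, trophic levels %.2f-%.2f, body mass up to %.3g\n",
              sum(x$is_sessile), min(x$TL), max(x$TL), max(x$mass)))
  invisible(x)
}
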