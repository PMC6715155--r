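#' Draw initial biomass densities
#'
#' Initial biomasses are i.i.d. uniform on `[b0_min, b0_max]` (default
#' `[0.05, 1]`, of the order of the plant carrying-capacity scale).  Paired
#' with/without-NTI runs reuse the same draw so that any end-state difference
#' is attributable to the non-trophic layers alone.
#'
#' @param S number of species.
#' @param b0_min,b0_max range of the uniform draw.
#' @return numeric vector of length `S`.
#' @export
draw_initial_biomasses <- function(S, b0_min = default_config()$b0_min,
                                   b0_max = default_config()$b0_max) {
  stopifnot(S >= 1, b0_min > 0, b0_max >= b0_min)
  stats::runif(S, b0_min, b0_max)
}

#' Flatten model parameters and NTI state for the compiled integrator
#'
#' Converts the matrix representation into link lists (0-based indices) as
#' consumed by the compiled right-hand side.  Exported mainly for testing;
#' [simulate_community()] calls it internally.
#'
#' @param params a `"model_params"`.
#' @param nti an `"nti_state"` (default: empty, pure trophic dynamics).
#' @return a plain list.
#' @export
build_sim_model <- function(params, nti = empty_nti_state(params)) {
  stopifnot(inherits(params, "model_params"), inherits(nti, "nti_state"),
            nti$S == params$S)
  links <- which(params$adjacency, arr.ind = TRUE)
  edge_list <- function(mat) {
    idx <- which(mat > 0, arr.ind = TRUE)
    list(src = as.integer(idx[, 1L] - 1L), tgt = as.integer(idx[, 2L] - 1L),
         w = mat[idx])
  }
  refuge <- edge_list(nti$phi)
  nmat <- edge_list(nti$n_mat)
  pmat <- edge_list(nti$p_mat)
  eta <- edge_list(nti$eta)
  ## gamma is stored [target i, source l]
  comp <- which(nti$gamma > 0, arr.ind = TRUE)
  delta <- edge_list(nti$delta)
  list(S = params$S,
       is_plant = as.integer(params$is_plant),
       m = params$m, r = params$r, K = params$K, x = params$x, d = params$d,
       w = params$w, q = params$q, i0_intra = nti$i0_intra,
       clamp_g = isTRUE(params$clamp_g),
       cons = as.integer(links[, 1L] - 1L),
       res = as.integer(links[, 2L] - 1L),
       a_base = params$a_base[links], h = params$h[links],
       eps = params$eps[links],
       ref_src = refuge$src, ref_tgt = refuge$tgt,
       n_src = nmat$src, n_tgt = nmat$tgt,
       p_src = pmat$src, p_tgt = pmat$tgt,
       eta_src = eta$src, eta_tgt = eta$tgt,
       comp_src = as.integer(comp[, 2L] - 1L),
       comp_tgt = as.integer(comp[, 1L] - 1L),
       comp_w = nti$gamma[comp],
       delta_src = delta$src, delta_tgt = delta$tgt, delta_w = delta$w,
       c0 = nti$c0, i0 = nti$i0, n0 = nti$n0, p0 = nti$p0,
       r0_refuge = nti$r0_refuge, e0 = nti$e0)
}

#' Integrate the community dynamics to the simulation horizon
#'
#' Advances the multiplex bioenergetic model with an embedded
#' Runge-Kutta-Fehlberg 4(5) integrator.  At every accepted step, any species
#' whose biomass has fallen below the extinction threshold is clamped to zero
#' and frozen; the state at `t_max` is treated as the steady state.
#'
#' @param params a `"model_params"`.
#' @param nti an `"nti_state"`; default empty (trophic-only run).
#' @param B0 strictly positive initial biomass vector (entries already below
#'   the threshold start extinct).
#' @param config an `"mws_config"` supplying `t_max`, the extinction
#'   threshold and solver tolerances; each can also be overridden directly.
#' @param t_max,threshold,rtol,atol solver controls (defaults from `config`).
#' @param sample_times optional increasing vector of times at which to record
#'   the trajectory (off by default to save memory).
#' @return an object of class `"sim_result"`: list with `B_final`, `alive`,
#'   `extinction_times` (NA for survivors), `diversity`, `t_end`, solver
#'   step counts and, if requested, `trajectory` (times x species) and
#'   `times`.
#' @examples
#' set.seed(7)
#' web <- generate_niche_web(30, 0.08, 6)
#' traits <- assign_traits(web, default_config(S = 30, n_sessile = 10))
#' params <- build_model_params(web, traits)
#' res <- simulate_community(params, B0 = draw_initial_biomasses(30),
#'                           config = default_config(t_max = 50))
#' res$diversity
#' @export
simulate_community <- function(params, nti = empty_nti_state(params), B0,
                               config = default_config(),
                               t_max = config$t_max,
                               threshold = config$ext_threshold,
                               rtol = config$rtol, atol = config$atol,
                               sample_times = numeric(0)) {
  stopifnot(length(B0) == params$S, all(is.finite(B0)), all(B0 >= 0),
            t_max > 0)
  model <- build_sim_model(params, nti)
  raw <- integrate_rkf45(model, as.numeric(B0), t_max, threshold,
                         rtol, atol, as.numeric(sample_times),
                         h_init = 1e-4, h_min = 1e-12, max_steps = 5e7)
  out <- list(B_final = raw$B_final, alive = raw$alive,
              extinction_times = raw$extinction_times,
              diversity = sum(raw$alive), t_end = raw$t_end,
              n_accepted = raw$n_accepted, n_rejected = raw$n_rejected)
  if (length(sample_times) > 0L) {
    out$trajectory <- raw$trajectory
    out$times <- as.numeric(sample_times)
  }
  structure(out, class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("community simulation to t = %g: %d of %d species surviving, total biomass %.4g\n",
              x$t_end, x$diversity, length(x$B_final), sum(x$B_final)))
  invisible(x)
}

## per-species production: first (growth) term of the biomass balance,
## g_i (r_i^new G_i + sum_j eps_ij F_ij - x_i) B_i
production_vector <- function(params, nti, B) {
  F_mat <- functional_response(params, nti, B)
  net <- effective_growth(params, nti, B) * (1 - B / params$K) +
    rowSums(params$eps * F_mat) - params$x
  competition_factor(params, nti, B, net) * net * B
}

#' Trophic-level classes used for per-level summaries
#'
#' Buckets prey-averaged trophic levels into primary producers (TL = 1),
#' low consumers (2 <= TL <= 3) and upper consumers (TL > 3).
#'
#' @param TL numeric trophic-level vector.
#' @return factor with levels `"TL=1"`, `"2<=TL<=3"`, `"TL>3"`.
#' @export
tl_class <- function(TL) {
  cls <- ifelse(TL < 1.5, "TL=1", ifelse(TL <= 3, "2<=TL<=3", "TL>3"))
  factor(cls, levels = c("TL=1", "2<=TL<=3", "TL>3"))
}

#' Steady-state community metrics
#'
#' From the final state of a simulation computes diversity (number of
#' surviving species), total biomass (summed over survivors) and total
#' production (the growth term of the biomass balance, i.e. intrinsic growth
#' of plants plus food uptake minus respiration of consumers, summed over
#' survivors), plus the same three metrics per trophic-level class.
#'
#' @param result a `"sim_result"`.
#' @param params the `"model_params"` used for the run.
#' @param nti the `"nti_state"` used for the run.
#' @param TL trophic-level vector (for the per-class breakdown).
#' @return an object of class `"community_metrics"`: list with `diversity`,
#'   `total_biomass`, `total_production` and `per_tl` (data frame, one row
#'   per class).
#' @export
compute_metrics <- function(result, params, nti = empty_nti_state(params),
                            TL) {
  B <- result$B_final
  alive <- result$alive
  prod <- production_vector(params, nti, B)
  prod[!alive] <- 0
  cls <- tl_class(TL)
  per_tl <- data.frame(
    class = levels(cls),
    diversity = as.integer(tapply(alive, cls, sum, default = 0)),
    biomass = as.numeric(tapply(B * alive, cls, sum, default = 0)),
    production = as.numeric(tapply(prod, cls, sum, default = 0)),
    row.names = NULL)
  structure(list(diversity = sum(alive),
                 total_biomass = sum(B[alive]),
                 total_production = sum(prod),
                 per_tl = per_tl),
            class = "community_metrics")
}

#' @export
print.community_metrics <- function(x, ...) {
  cat(sprintf("diversity %d, biomass %.4g, production %.4g\n",
              x$diversity, x$total_biomass, x$total_production))
  print(x$per_tl, row.names = FALSE)
  invisible(x)
}

#' Normalized with/without ratio
#'
#' `(with - without) / without`: the relative change of a steady-state metric
#' caused by the non-trophic layers, e.g. the diversity ratio of paired
#' simulations.  Undefined (NA) when the reference value is not positive.
#'
#' @param metric_with,metric_without metric values from the paired runs.
#' @return numeric scalar (or vector, elementwise), `NA` where
#'   `metric_without <= 0`.
#' @export
normalized_ratio <- function(metric_with, metric_without) {
  ifelse(metric_without > 0, (metric_with - metric_without) / metric_without,
         NA_real_)
}
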