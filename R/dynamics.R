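#' Refuge-modified capture coefficients
#'
#' Refuge provisioning shelters a prey from all of its consumers: the capture
#' coefficient on every trophic link towards prey `j` is divided by
#' \eqn{1 + r_0 \sum_k \phi_{kj} B_k}, so it tends to 0 as facilitator
#' biomass grows.
#'
#' @param params a `"model_params"`.
#' @param nti an `"nti_state"`.
#' @param B nonnegative biomass vector.
#' @return S x S matrix of effective capture coefficients.
#' @export
effective_attack <- function(params, nti, B) {
  refsum <- as.numeric(crossprod(nti$phi, B))      # per prey j
  sweep(params$a_base, 2L, 1 + nti$r0_refuge * refsum, "/")
}

#' Mortality rates under positive and negative non-trophic effects
#'
#' \eqn{d_i^{new} = d_i (1 + n_0 \sum_k n_{ki} B_k) /
#' (1 + p_0 \sum_k p_{ki} B_k)}: effectors can raise (whiplash-like damage)
#' or lower (environmental amelioration) background mortality.
#'
#' @inheritParams effective_attack
#' @return vector of effective mortality rates.
#' @export
effective_mortality <- function(params, nti, B) {
  up   <- as.numeric(crossprod(nti$n_mat, B))
  down <- as.numeric(crossprod(nti$p_mat, B))
  params$d * (1 + nti$n0 * up) / (1 + nti$p0 * down)
}

#' Growth rates under recruitment facilitation
#'
#' \eqn{r_i^{new} = r_i (1 + e_0 \sum_k \eta_{ki} B_k)}.  Facilitation
#' targets plants only (the recruitment layer's eligibility rule), so
#' consumers keep \eqn{r_i = 0}.
#'
#' @inheritParams effective_attack
#' @return vector of effective intrinsic growth rates.
#' @export
effective_growth <- function(params, nti, B) {
  params$r * (1 + nti$e0 * as.numeric(crossprod(nti$eta, B)))
}

#' Multi-prey functional response with predator interference
#'
#' Feeding rate of consumer `i` on resource `j`:
#' \deqn{F_{ij} = \frac{w_i a_{ij} B_j^{1+q}}
#'   {m_i (1 + i_{0,intra} B_i + i_0 \sum_{s \in pred(j), s \neq i}
#'    \delta_{si} B_s + w_i \sum_{k \in diet(i)} a_{ik} h_{ik} B_k^{1+q})}}
#' a Hill-exponent (1+q) saturating response with Beddington-DeAngelis
#' interference summed over the other predators of the focal prey, plus an
#' always-active intraspecific interference term.  Capture coefficients are
#' the refuge-modified ones.
#'
#' @inheritParams effective_attack
#' @return S x S matrix `F` with `F[i, j]` the per-unit-biomass feeding rate
#'   of `i` on `j`; zero off the trophic adjacency.
#' @export
functional_response <- function(params, nti, B) {
  S <- params$S
  Bq <- pmax(B, 0)^(1 + params$q)
  a_new <- effective_attack(params, nti, B)
  handling <- params$w * as.numeric((a_new * params$h) %*% Bq)   # per consumer
  ## interference: T[i, j] = sum_s delta[s, i] B_s over predators s of j
  interf <- nti$i0 * crossprod(nti$delta * B, params$adjacency * 1)
  denom <- 1 + nti$i0_intra * B + interf + handling  # recycles per-row terms
  num <- (params$w / params$m) * a_new *
    matrix(Bq, S, S, byrow = TRUE)
  F_mat <- num / denom
  F_mat[!params$adjacency] <- 0
  F_mat
}

#' Competition-for-space factor
#'
#' \eqn{g_i = 1 - c_0 \sum_l \gamma_{il} B_l} when the target's net growth
#' rate is positive, otherwise 1 (space competition can depress growth but
#' does not add mortality).  `gamma` rows are zero for mobile species, which
#' therefore always have `g = 1`.  By default the factor is treated as a
#' growth-reduction factor bounded in `[0, 1]`: heavy sessile competitors can
#' otherwise drive it far below zero during transients, turning the growth
#' term into a strong unintended decay (set `clamp_g = FALSE` in the
#' configuration for the unclamped linear form).
#'
#' @inheritParams effective_attack
#' @param net_growth per-species net growth rate
#'   \eqn{r_i^{new} G_i + \sum_j \epsilon_{ij} F_{ij} - x_i}.
#' @return vector of multiplicative growth factors.
#' @export
competition_factor <- function(params, nti, B, net_growth) {
  g <- rep(1, params$S)
  if (nti$c0 > 0) {
    comp <- as.numeric(nti$gamma %*% B)
    pos <- net_growth > 0
    g[pos] <- 1 - nti$c0 * comp[pos]
    if (isTRUE(params$clamp_g)) g <- pmax(g, 0)
  }
  g
}

#' Right-hand side of the multiplex bioenergetic model
#'
#' \deqn{\frac{dB_i}{dt} = g_i (r_i^{new} G_i +
#'   \sum_{j} \epsilon_{ij} F_{ij} - x_i) B_i -
#'   \sum_{k} B_k F_{ki} - d_i^{new} B_i}
#' with logistic plant growth \eqn{G_i = 1 - B_i / K_i}.  With all six NTI
#' intensities at zero the equation reduces term by term to the plain
#' trophic bioenergetic model.  Extinct species (B = 0) have derivative 0:
#' zero biomass is absorbing.
#'
#' @inheritParams effective_attack
#' @return vector `dB/dt`.
#' @export
rhs <- function(params, nti, B) {
  if (any(!is.finite(B))) stop("non-finite biomass passed to rhs()")
  F_mat <- functional_response(params, nti, B)
  G <- 1 - B / params$K
  net <- effective_growth(params, nti, B) * G +
    rowSums(params$eps * F_mat) - params$x
  g <- competition_factor(params, nti, B, net)
  dB <- g * net * B - as.numeric(crossprod(F_mat, B)) -
    effective_mortality(params, nti, B) * B
  dB[B <= 0] <- 0
  dB
}
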