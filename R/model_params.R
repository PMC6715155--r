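#' Assemble allometric model parameters for a web
#'
#' Populates every rate constant of the bioenergetic model from body mass and
#' the configuration:
#' \itemize{
#'   \item intrinsic growth \eqn{r_i = r_0 m_i^{-0.25}} (plants; 0 otherwise);
#'   \item carrying capacity \eqn{K_i = K_0 m_i^{0.25}};
#'   \item metabolic demand \eqn{x_i = x_{other} m_i^{-0.25}} (consumers; 0
#'     for plants, whose maintenance is folded into \eqn{r_i});
#'   \item background mortality \eqn{d_i = d_0 x_{species} m_i^{-0.25}} with
#'     the plant or consumer metabolic coefficient;
#'   \item assimilation efficiency 0.45 on plant resources, 0.85 otherwise;
#'   \item relative consumption \eqn{w_i = 1 / |diet_i|}, fixed at the
#'     structural (initial) diet for the whole run;
#'   \item capture coefficients with three mobility cases: both species
#'     mobile, \eqn{a_0 m_i^{exp1} m_j^{exp2}}; sessile consumer,
#'     \eqn{a_{0,sesscons} m_j^{exp2}}; sessile resource (mobile consumer),
#'     \eqn{a_{0,sessres} m_i^{exp1}};
#'   \item handling time \eqn{h_{ij} = h_0 m_i^{-0.48} m_j^{-0.66}}.
#' }
#' Matrix-valued parameters are zero off the trophic adjacency.
#'
#' @param web a `"trophic_web"`.
#' @param traits a `"species_traits"` (body masses must be present).
#' @param config an `"mws_config"`.
#' @return an object of class `"model_params"`.
#' @export
build_model_params <- function(web, traits, config = default_config()) {
  S <- web$S
  m <- traits$mass
  if (is.null(m) || any(!is.finite(m)) || any(m <= 0)) {
    stop("traits must carry positive finite body masses")
  }
  validate_config(config)
  is_plant <- web$is_plant
  adj <- web$adjacency

  r <- ifelse(is_plant, config$r0 * m^-0.25, 0)
  K <- config$K0 * m^0.25
  x <- ifelse(is_plant, 0, config$x_other * m^-0.25)
  d <- config$d0 * ifelse(is_plant, config$x_plant, config$x_other) * m^-0.25

  diet_size <- rowSums(adj)
  w <- ifelse(diet_size > 0L, 1 / pmax(diet_size, 1L), 0)

  eps <- matrix(0, S, S)
  eps[, is_plant]  <- config$eps_plant
  eps[, !is_plant] <- config$eps_other
  eps[!adj] <- 0

  ## capture coefficient, by consumer/resource mobility
  cons_sessile <- matrix(traits$is_sessile, S, S)          # rows: consumer i
  res_sessile  <- matrix(traits$is_sessile, S, S, byrow = TRUE)
  mi_e1 <- matrix(m^config$exp1, S, S)
  mj_e2 <- matrix(m^config$exp2, S, S, byrow = TRUE)
  a_base <- config$a0 * mi_e1 * mj_e2
  a_base[cons_sessile] <- (config$a0_sesscons * mj_e2)[cons_sessile]
  a_base[!cons_sessile & res_sessile] <-
    (config$a0_sessres * mi_e1)[!cons_sessile & res_sessile]
  a_base[!adj] <- 0

  h <- config$h0 * outer(m^config$h_exp_cons, m^config$h_exp_res)
  h[!adj] <- 0

  structure(
    list(S = S, is_plant = is_plant, is_sessile = traits$is_sessile,
         adjacency = adj, m = m, r = r, K = K, x = x, d = d,
         eps = eps, w = w, a_base = a_base, h = h, q = config$q,
         i0_intra = config$i0_intra, clamp_g = isTRUE(config$clamp_g)),
    class = "model_params")
}

#' Assemble the non-trophic interaction state
#'
#' Converts the NTI layers of a multiplex network into the weighted matrices
#' entering the dynamical equations:
#' \itemize{
#'   \item competition weights \eqn{\gamma_{il} = \gamma_0 m_l^{2/3}} on
#'     present competition links (effect of source `l` on target `i`);
#'   \item interference weights
#'     \eqn{\delta_{si} = 1 / (1 + |\ln m_s - \ln m_i|)} on present
#'     interference links (stronger between similar-sized predators);
#'   \item presence matrices for refuge (`phi`), recruitment (`eta`) and
#'     mortality effects (`n_mat`, `p_mat`), all indexed `[source, target]`.
#' }
#' Each mechanism's intensity is taken from its layer; a missing layer leaves
#' the mechanism off.  Intraspecific interference `i0_intra` is always
#' active, independent of the layers.
#'
#' @param mx a `"multiplex"`.
#' @param config an `"mws_config"` (supplies `gamma0` and `i0_intra`).
#' @return an object of class `"nti_state"`.
#' @export
build_nti_state <- function(mx, config = default_config()) {
  S <- mx$web$S
  m <- mx$traits$mass
  zero <- matrix(0, S, S)
  st <- list(S = S,
             gamma = zero, delta = zero, phi = zero, eta = zero,
             n_mat = zero, p_mat = zero,
             c0 = 0, i0 = 0, n0 = 0, p0 = 0, r0_refuge = 0, e0 = 0,
             i0_intra = config$i0_intra)
  for (layer in mx$layers) {
    pr <- layer$presence * 1
    switch(layer$nti_type,
      competition = {
        ## gamma[i, l]: weight of source l acting on target i
        st$gamma <- t(pr) * matrix(config$gamma0 * m^(2 / 3), S, S, byrow = TRUE)
        st$c0 <- layer$intensity
      },
      interference = {
        st$delta <- pr / (1 + abs(outer(log(m), log(m), "-")))
        st$i0 <- layer$intensity
      },
      mortality_increase = {
        st$n_mat <- pr
        st$n0 <- layer$intensity
      },
      mortality_decrease = {
        st$p_mat <- pr
        st$p0 <- layer$intensity
      },
      refuge = {
        st$phi <- pr
        st$r0_refuge <- layer$intensity
      },
      recruitment = {
        st$eta <- pr
        st$e0 <- layer$intensity
      })
  }
  structure(st, class = "nti_state")
}

#' An empty non-trophic state (pure trophic dynamics)
#'
#' @param params a `"model_params"` (supplies `S` and `i0_intra`).
#' @return an `"nti_state"` with all layers empty and all intensities zero
#'   except the always-active intraspecific interference.
#' @export
empty_nti_state <- function(params) {
  S <- params$S
  zero <- matrix(0, S, S)
  structure(list(S = S, gamma = zero, delta = zero, phi = zero, eta = zero,
                 n_mat = zero, p_mat = zero,
                 c0 = 0, i0 = 0, n0 = 0, p0 = 0, r0_refuge = 0, e0 = 0,
                 i0_intra = params$i0_intra),
            class = "nti_state")
}
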