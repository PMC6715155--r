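## Ensemble experiments: paired with/without-NTI simulations over generated
## webs, with the end-of-dynamics "no disconnected plant" filter.
##
## Under the default parameter set the strict filter (every surviving plant
## keeps a surviving consumer) is satisfied by essentially no generated web,
## because consumers on high trophic levels are energetically marginal and
## several plants lose all their consumers in every run.  Rejection sampling
## on the strict predicate therefore does not terminate.  The ensembles use
## a soft policy instead: a handful of candidate webs (or layer draws) are
## tried against the strict filter, and if none passes the candidate with
## the fewest disconnected plants is kept, with the count recorded in the
## output so downstream analyses can condition on it.

count_disconnected_plants <- function(web, alive) {
  sum(vapply(which(web$is_plant & alive), function(i) {
    !any(alive & web$adjacency[, i])
  }, logical(1)))
}

## Generate one study web: niche web + traits + parameters + shared initial
## biomasses + its trophic-only baseline run.  Paired with-NTI runs reuse B0
## and the baseline.
accepted_web <- function(config, filter_attempts = 3L) {
  best <- NULL
  for (k in seq_len(max(filter_attempts, 1L))) {
    web <- generate_niche_web(config$S, config$connectance, config$n_plants,
                              config$max_attempts)
    traits <- assign_traits(web, config)
    params <- build_model_params(web, traits, config)
    B0 <- draw_initial_biomasses(config$S, config$b0_min, config$b0_max)
    base <- simulate_community(params, B0 = B0, config = config)
    n_disc <- count_disconnected_plants(web, base$alive)
    cand <- list(web = web, traits = traits, params = params, B0 = B0,
                 base = base, n_disconnected = n_disc, attempts = k)
    if (n_disc == 0L) { best <- cand; break }
    if (is.null(best) || n_disc < best$n_disconnected) best <- cand
  }
  best$base_metrics <- compute_metrics(best$base, best$params,
                                       TL = best$traits$TL)
  best
}

## Run the with-NTI arm for a set of layers; returns metrics plus the
## disconnected-plant count of the run.
run_with_arm <- function(aw, layers, config) {
  nti <- build_nti_state(multiplex_network(aw$web, aw$traits, layers), config)
  res <- simulate_community(aw$params, nti, aw$B0, config)
  list(result = res,
       metrics = compute_metrics(res, aw$params, nti, aw$traits$TL),
       n_disconnected = count_disconnected_plants(aw$web, res$alive))
}

ratio_row <- function(mw, m0) {
  data.frame(
    diversity_with = mw$diversity, diversity_without = m0$diversity,
    biomass_with = mw$total_biomass, biomass_without = m0$total_biomass,
    production_with = mw$total_production,
    production_without = m0$total_production,
    diversity_ratio = normalized_ratio(mw$diversity, m0$diversity),
    biomass_ratio = normalized_ratio(mw$total_biomass, m0$total_biomass),
    production_ratio = normalized_ratio(mw$total_production,
                                        m0$total_production))
}

scaled_n <- function(n, scale_factor) max(1L, as.integer(round(n * scale_factor)))

#' Single-NTI intensity sweeps
#'
#' For each NTI type separately: over accepted webs and repeated layer
#' draws, runs paired with/without simulations along a linear grid of
#' interaction intensities, and summarises the mean metric ratios per
#' intensity together with the OLS slope of the diversity ratio on intensity
#' (the per-type interaction-strength indicator).
#'
#' Layer draws whose with-NTI run ends with a disconnected plant are
#' resampled up to `max_redraws`; a draw still failing then is kept but
#' flagged `plant_ok = FALSE` and excluded from the summaries.
#'
#' @param types NTI types to sweep (default all six).
#' @param n_webs accepted webs per type.
#' @param n_draws layer draws per web.
#' @param grid_size intensities per sweep, evenly spaced over the calibrated
#'   range of the type.
#' @param config an `"mws_config"`; its `intensity_ranges` define the grids.
#' @param seed optional integer seed.
#' @param scale_factor in `(0, 1]`, scales `n_webs` and `n_draws` for
#'   desk-scale runs.
#' @return an object of class `"nti_sweep"`: list with `runs` (one row per
#'   web x draw x intensity, including the per-run disconnected-plant
#'   count), `by_intensity` (mean ratios) and `slopes` (per-type
#'   `"regression_fit"` of diversity ratio on intensity).
#' @export
run_single_nti_sweep <- function(types = nti_types, n_webs = 20L,
                                 n_draws = 10L, grid_size = 8L,
                                 config = default_config(), seed = NULL,
                                 scale_factor = 1) {
  if (!is.null(seed)) set.seed(seed)
  n_webs <- scaled_n(n_webs, scale_factor)
  n_draws <- scaled_n(n_draws, scale_factor)
  rows <- list()
  for (ty in types) {
    rg <- config$intensity_ranges[[ty]]
    grid <- seq(rg[1], rg[2], length.out = grid_size)
    for (wi in seq_len(n_webs)) {
      aw <- accepted_web(config)
      for (di in seq_len(n_draws)) {
        layer <- draw_nti_layer(aw$web, aw$traits, ty, config$p_nti[[ty]], 0)
        for (gi in seq_along(grid)) {
          layer$intensity <- grid[gi]
          arm <- run_with_arm(aw, list(layer), config)
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(type = ty, web = wi, draw = di,
                       intensity = grid[gi], n_links = layer$n_links,
                       disconnected_plants = arm$n_disconnected),
            ratio_row(arm$metrics, aw$base_metrics))
        }
      }
    }
  }
  runs <- do.call(rbind, rows)
  by_intensity <- stats::aggregate(
    runs[c("diversity_ratio", "biomass_ratio", "production_ratio")],
    by = runs[c("type", "intensity")], FUN = mean, na.rm = TRUE)
  slopes <- lapply(split(runs, runs$type), function(d) {
    fit_linear(d$intensity, d$diversity_ratio)
  })
  structure(list(runs = runs, by_intensity = by_intensity, slopes = slopes),
            class = "nti_sweep")
}

#' @export
print.nti_sweep <- function(x, ...) {
  cat("single-NTI intensity sweep:", nrow(x$runs), "paired runs\n")
  for (ty in names(x$slopes)) {
    cat(sprintf("  %-18s slope of diversity ratio on intensity: %+.4g\n",
                ty, x$slopes[[ty]]$slope))
  }
  invisible(x)
}

#' Mixed-NTI ensemble
#'
#' The joint-effect experiment: all five retained NTI types together
#' (decrease in mortality excluded for its negligible individual effect),
#' with intensities drawn uniformly in their calibrated ranges per run and
#' the four negative types drawn at one quarter of their single-type link
#' probabilities, so positive (recruitment) and negative non-trophic links
#' are equally abundant (about 100 each).
#'
#' @param n_webs accepted webs.
#' @param n_draws layer/intensity draws per web.
#' @param config an `"mws_config"`.
#' @param seed optional integer seed.
#' @param scale_factor in `(0, 1]`, scales the ensemble size.
#' @return data frame, one row per run: drawn intensities, realized link
#'   counts, paired metrics, ratios and the run's disconnected-plant count.
#' @export
run_mixed_ensemble <- function(n_webs = 50L, n_draws = 10L,
                               config = default_config(), seed = NULL,
                               scale_factor = 1) {
  if (!is.null(seed)) set.seed(seed)
  n_webs <- scaled_n(n_webs, scale_factor)
  n_draws <- scaled_n(n_draws, scale_factor)
  types <- setdiff(nti_types, "mortality_decrease")
  negative <- setdiff(types, "recruitment")
  prob <- config$p_nti
  prob[negative] <- prob[negative] / 4
  rows <- list()
  for (wi in seq_len(n_webs)) {
    aw <- accepted_web(config)
    for (di in seq_len(n_draws)) {
      inten <- vapply(types, function(ty) {
        rg <- config$intensity_ranges[[ty]]
        stats::runif(1, rg[1], rg[2])
      }, numeric(1))
      layers <- lapply(types, function(ty) {
        draw_nti_layer(aw$web, aw$traits, ty, prob[[ty]], inten[[ty]])
      })
      arm <- run_with_arm(aw, layers, config)
      links <- vapply(layers, function(l) l$n_links, numeric(1))
      names(links) <- paste0("links_", types)
      names(inten) <- paste0("intensity_", types)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(web = wi, draw = di,
                   disconnected_plants = arm$n_disconnected),
        as.data.frame(as.list(inten)), as.data.frame(as.list(links)),
        ratio_row(arm$metrics, aw$base_metrics))
    }
  }
  do.call(rbind, rows)
}

#' Link-count ensemble
#'
#' Fixes every NTI intensity at its calibrated maximum (10% individual
#' effect on diversity) and varies the relative abundance of positive
#' (recruitment) versus negative non-trophic links: link-count setups are
#' given as `c(positive, negative)` targets, scaled against the reference of
#' 100 links per side.  The negative-side probability budget is split evenly
#' over the negative types present in `combo`.
#'
#' @param setups list of `c(pos, neg)` link-count targets.
#' @param combo NTI types to include (default: recruitment plus the four
#'   negative types).
#' @param n_webs,n_draws ensemble size per setup.
#' @param config an `"mws_config"`.
#' @param seed optional integer seed.
#' @param scale_factor in `(0, 1]`.
#' @return data frame with one row per run: setup label, realized link
#'   counts, paired ratios and the run's disconnected-plant count.
#' @export
run_link_count_ensemble <- function(setups = list(c(100, 100), c(50, 100),
                                                  c(100, 50)),
                                    combo = setdiff(nti_types,
                                                    "mortality_decrease"),
                                    n_webs = 20L, n_draws = 5L,
                                    config = default_config(), seed = NULL,
                                    scale_factor = 1) {
  if (!is.null(seed)) set.seed(seed)
  n_webs <- scaled_n(n_webs, scale_factor)
  n_draws <- scaled_n(n_draws, scale_factor)
  max_int <- c(competition = config$intensity_ranges$competition[2],
               interference = config$intensity_ranges$interference[2],
               mortality_increase = config$intensity_ranges$mortality_increase[2],
               refuge = config$intensity_ranges$refuge[2],
               recruitment = config$intensity_ranges$recruitment[2])
  negative <- intersect(combo, c("competition", "interference",
                                 "mortality_increase", "refuge"))
  positive <- intersect(combo, "recruitment")
  rows <- list()
  for (si in seq_along(setups)) {
    tgt <- setups[[si]]
    label <- sprintf("%d+/%d-", tgt[1], tgt[2])
    prob <- numeric(0)
    for (ty in positive) prob[ty] <- config$p_nti[[ty]] * tgt[1] / 100
    for (ty in negative) {
      prob[ty] <- config$p_nti[[ty]] * (tgt[2] / 100) / length(negative)
    }
    for (wi in seq_len(n_webs)) {
      aw <- accepted_web(config)
      for (di in seq_len(n_draws)) {
        layers <- lapply(names(prob), function(ty) {
          draw_nti_layer(aw$web, aw$traits, ty, prob[[ty]], max_int[[ty]])
        })
        arm <- run_with_arm(aw, layers, config)
        links <- vapply(layers, function(l) l$n_links, numeric(1))
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(setup = label, web = wi, draw = di,
                     links_positive = sum(links[match(positive, names(prob))]),
                     links_negative = sum(links[match(negative, names(prob))]),
                     disconnected_plants = arm$n_disconnected),
          ratio_row(arm$metrics, aw$base_metrics))
      }
    }
  }
  do.call(rbind, rows)
}

#' Sensitivity suite for the diversity-functioning slope
#'
#' Repeats the mixed ensemble under alternative values of the three most
#' influential parameters, varied one at a time -- the Hill coefficient
#' (`q` = 0.3, 0.7), the capture coefficient (`a0` = 10 with `h0` = 0.1 to
#' avoid massive extinctions, and 250) and the mass ratio per trophic level
#' (`expo` = 25, 75) -- and reports, per setting, the OLS slope of total
#' biomass on diversity with and without NTIs and the ANCOVA p-value for
#' their difference.
#'
#' @param settings named list of config-override lists; the default is the
#'   grid above plus the reference setting.
#' @param n_webs,n_draws ensemble size per setting.
#' @param config base configuration to override.
#' @param seed optional integer seed.
#' @param scale_factor in `(0, 1]`.
#' @return list with `slopes` (data frame: setting, slope_without,
#'   slope_with, ancova_p, n_runs) and `ensembles` (per-setting run tables).
#' @export
run_sensitivity_suite <- function(settings = NULL, n_webs = 10L, n_draws = 5L,
                                  config = default_config(), seed = NULL,
                                  scale_factor = 1) {
  if (is.null(settings)) {
    settings <- list(default = list(),
                     q_low = list(q = 0.3), q_high = list(q = 0.7),
                     a0_low = list(a0 = 10, a0_sesscons = 10, a0_sessres = 10,
                                   h0 = 0.1),
                     a0_high = list(a0 = 250, a0_sesscons = 250,
                                    a0_sessres = 250),
                     expo_low = list(expo = 25), expo_high = list(expo = 75))
  }
  if (!is.null(seed)) set.seed(seed)
  ensembles <- list()
  out <- list()
  for (nm in names(settings)) {
    cfg <- override_config(config, settings[[nm]])
    ens <- run_mixed_ensemble(n_webs, n_draws, cfg,
                              scale_factor = scale_factor)
    ensembles[[nm]] <- ens
    fit_wo <- fit_linear(ens$diversity_without, ens$biomass_without)
    fit_wi <- fit_linear(ens$diversity_with, ens$biomass_with)
    anc <- ancova_slopes(ens$diversity_without, ens$biomass_without,
                         ens$diversity_with, ens$biomass_with)
    out[[nm]] <- data.frame(setting = nm,
                            slope_without = fit_wo$slope,
                            slope_with = fit_wi$slope,
                            ancova_p = anc$p_value, n_runs = nrow(ens))
  }
  list(slopes = do.call(rbind, c(out, list(make.row.names = FALSE))),
       ensembles = ensembles)
}

#' Calibrate an NTI intensity to a target diversity effect
#'
#' Finds, by bisection, the intensity at which the mean diversity ratio of a
#' fixed calibration ensemble (same webs, layer draws and initial biomasses
#' at every evaluation) reaches a target magnitude, e.g. the 2.5% and 10%
#' endpoints that define the calibrated intensity ranges.  If the target is
#' unreachable within `bounds` (as for decreases in mortality, whose effect
#' saturates), the result reports the maximum achieved effect instead.
#'
#' @param nti_type one of [nti_types].
#' @param target_effect signed target diversity ratio, `0 < |target| < 0.5`.
#' @param config an `"mws_config"`.
#' @param n_webs,n_draws calibration-ensemble size.
#' @param tol absolute tolerance on the mean diversity ratio.
#' @param bounds intensity search interval (default: 0 to twice the
#'   calibrated range maximum of the type).
#' @param max_iter bisection iteration cap.
#' @param seed optional integer seed.
#' @return list with `intensity`, `achieved` (mean diversity ratio at the
#'   returned intensity), `converged`, `evaluations` (data frame of all
#'   probed intensities).
#' @export
calibrate_intensity <- function(nti_type, target_effect,
                                config = default_config(),
                                n_webs = 20L, n_draws = 5L, tol = 0.005,
                                bounds = NULL, max_iter = 20L, seed = NULL) {
  nti_type <- match.arg(nti_type, nti_types)
  stopifnot(abs(target_effect) > 0 || target_effect == 0,
            abs(target_effect) < 0.5)
  if (!is.null(seed)) set.seed(seed)
  if (target_effect == 0) {
    return(list(intensity = 0, achieved = 0, converged = TRUE,
                evaluations = data.frame(intensity = 0, mean_ratio = 0)))
  }
  if (is.null(bounds)) {
    bounds <- c(0, 2 * config$intensity_ranges[[nti_type]][2])
  }
  ## fixed calibration ensemble: webs, layer topologies and B0 never change
  ## across evaluations, so the mean ratio is a deterministic function of
  ## the intensity
  ens <- list()
  for (wi in seq_len(n_webs)) {
    aw <- accepted_web(config)
    draws <- lapply(seq_len(n_draws), function(d) {
      draw_nti_layer(aw$web, aw$traits, nti_type, config$p_nti[[nti_type]], 0)
    })
    ens[[wi]] <- list(aw = aw, draws = draws)
  }
  mean_ratio_at <- function(intensity) {
    vals <- numeric(0)
    for (e in ens) {
      for (layer in e$draws) {
        layer$intensity <- intensity
        nti <- build_nti_state(
          multiplex_network(e$aw$web, e$aw$traits, list(layer)), config)
        res <- simulate_community(e$aw$params, nti, e$aw$B0, config)
        vals <- c(vals, normalized_ratio(res$diversity, e$aw$base$diversity))
      }
    }
    mean(vals, na.rm = TRUE)
  }
  evals <- data.frame(intensity = numeric(0), mean_ratio = numeric(0))
  probe <- function(x) {
    v <- mean_ratio_at(x)
    evals[nrow(evals) + 1L, ] <<- c(x, v)
    v
  }
  tgt <- abs(target_effect)
  hi <- bounds[2]
  f_hi <- probe(hi)
  if (abs(f_hi) < tgt - tol) {
    return(list(intensity = hi, achieved = f_hi, converged = FALSE,
                evaluations = evals))
  }
  lo <- bounds[1]
  f_lo <- if (lo == 0) 0 else probe(lo)
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- probe(mid)
    if (abs(abs(f_mid) - tgt) <= tol) {
      return(list(intensity = mid, achieved = f_mid, converged = TRUE,
                  evaluations = evals))
    }
    if (abs(f_mid) < tgt) lo <- mid else hi <- mid
  }
  list(intensity = (lo + hi) / 2, achieved = probe((lo + hi) / 2),
       converged = FALSE, evaluations = evals)
}
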