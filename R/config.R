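#' Default model and experiment configuration
#'
#' Returns the full set of constants used by the bioenergetic multiplex model:
#' allometric rate coefficients, functional-response parameters, the six
#' non-trophic interaction (NTI) intensities and their calibrated ranges,
#' network-generation settings and solver controls.  Every value can be
#' overridden, either via `...` here or through [load_config()].
#'
#' Units follow the bioenergetic convention in which the plant growth scaling
#' `r0` fixes the time scale and the carrying-capacity scaling `K0` the
#' biomass-density scale; body masses are expressed relative to a plant of
#' mass 1.
#'
#' @param ... named overrides of any default entry.  Unknown names are an
#'   error, so typos cannot silently fall through to defaults.
#' @return a named list of class `"mws_config"`.
#' @examples
#' cfg <- default_config(q = 0.3)
#' cfg$q
#' @export
default_config <- function(...) {
  cfg <- list(
    ## -- network generation ------------------------------------------------
    S            = 100L,   # species per web
    connectance  = 0.06,   # target directed connectance L / S^2
    n_plants     = 20L,    # basal species per web (enforced exactly)
    n_sessile    = 33L,    # sessile species per web (enforced exactly)
    p_sessile_plant = 0.8, # per-species sessile probability, plants
    p_sessile_other = 0.2, # per-species sessile probability, consumers
    max_attempts = 10000L, # rejection-sampling cap (webs and trait draws)
    ## per-type NTI link probabilities (single-type layers)
    p_nti = c(competition        = 0.098,
              interference       = 0.15,
              mortality_increase = 0.01,
              mortality_decrease = 0.01,
              refuge             = 0.033,
              recruitment        = 0.063),

    ## -- allometric scalings ----------------------------------------------
    r0       = 1,      # plant intrinsic-growth scaling, r_i = r0 m^-0.25
    K0       = 1,      # carrying-capacity scaling,      K_i = K0 m^0.25
    x_plant  = 0.138,  # metabolic coefficient entering plant mortality
    x_other  = 0.314,  # metabolic coefficient, consumers (demand + mortality)
    d0       = 0.1,    # mortality scaling, d_i = d0 x_species m^-0.25
    eps_plant = 0.45,  # assimilation efficiency eating a plant
    eps_other = 0.85,  # assimilation efficiency eating a consumer
    a0          = 50,  # capture coefficient, both species mobile
    a0_sesscons = 50,  # capture coefficient, sessile consumer
    a0_sessres  = 50,  # capture coefficient, sessile resource
    exp1 = 0.45,       # consumer-mass exponent in the capture coefficient
    exp2 = 0.15,       # resource-mass exponent in the capture coefficient
    h0   = 0.3,        # handling-time scaling, h_ij = h0 m_i^-0.48 m_j^-0.66
    h_exp_cons = -0.48,
    h_exp_res  = -0.66,
    q    = 0.5,        # Hill coefficient; 1+q is the Hill exponent
    expo = 50,         # body-mass base, m_i = expo^(TL_i - 1)
    gamma0 = 1,        # competition-weight scaling, gamma_il = gamma0 m_l^(2/3)
    clamp_g = TRUE,    # competition factor bounded in [0, 1] (growth reduction)
    i0_intra = 0.8,    # intraspecific predator interference, always active

    ## -- NTI intensities (defaults 0 = mechanism off) ----------------------
    c0 = 0, i0 = 0, n0 = 0, p0 = 0, r0_refuge = 0, e0 = 0,
    ## calibrated intensity ranges: |diversity ratio| 2.5% (min) to 10% (max)
    intensity_ranges = list(
      competition        = c(0.0045, 0.012),
      interference       = c(0.75,   3),
      mortality_increase = c(0.75,   3),
      mortality_decrease = c(5,      20),
      refuge             = c(0.25,   1.75),
      recruitment        = c(0.15,   1.8)),

    ## -- simulation --------------------------------------------------------
    t_max      = 5000,   # integration horizon; final state is "steady state"
    ext_threshold = 1e-6, # biomass below which a species is clamped extinct
    rtol = 1e-8,
    atol = 1e-10,
    b0_min = 0.05,       # initial biomass draw, uniform on [b0_min, b0_max]
    b0_max = 1.0
  )
  override_config(structure(cfg, class = "mws_config"), list(...))
}

## apply named overrides, refusing unknown keys
override_config <- function(cfg, overrides) {
  if (length(overrides) == 0L) return(cfg)
  nm <- names(overrides)
  if (is.null(nm) || any(nm == "")) stop("config overrides must be named")
  unknown <- setdiff(nm, names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in nm) {
    v <- overrides[[k]]
    if (k == "p_nti") {
      bad <- setdiff(names(v), names(cfg$p_nti))
      if (length(bad)) stop("unknown NTI type in p_nti: ", paste(bad, collapse = ", "))
      cfg$p_nti[names(v)] <- unlist(v)
    } else if (k == "intensity_ranges") {
      bad <- setdiff(names(v), names(cfg$intensity_ranges))
      if (length(bad)) stop("unknown NTI type in intensity_ranges: ", paste(bad, collapse = ", "))
      cfg$intensity_ranges[names(v)] <- v
    } else {
      cfg[[k]] <- v
    }
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$S >= 2, cfg$n_plants >= 1, cfg$n_plants < cfg$S,
    cfg$connectance > 0, cfg$connectance < 1,
    cfg$n_sessile <= cfg$S,
    all(cfg$p_nti >= 0), all(cfg$p_nti <= 1),
    cfg$t_max > 0, cfg$ext_threshold > 0,
    cfg$b0_min > 0, cfg$b0_max >= cfg$b0_min
  )
  for (key in c("h0", "a0", "a0_sesscons", "a0_sessres", "expo", "gamma0",
                "r0", "K0", "d0")) {
    if (cfg[[key]] <= 0) stop("config key '", key, "' must be positive")
  }
  for (key in c("c0", "i0", "n0", "p0", "r0_refuge", "e0", "i0_intra")) {
    if (cfg[[key]] < 0) stop("config key '", key, "' must be nonnegative")
  }
  invisible(cfg)
}

#' Load a configuration file
#'
#' Reads a key-value configuration file (YAML if the `yaml` package is
#' available and the file has a `.yml`/`.yaml` extension, otherwise
#' `key = value` pairs parseable as R literals, one per line, `#` comments
#' allowed) and merges it over [default_config()].  Unknown keys are rejected
#' with the offending key named.
#'
#' @param path file path; an empty or missing file yields the full defaults.
#' @return an `"mws_config"` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml") && requireNamespace("yaml", quietly = TRUE)) {
    overrides <- yaml::read_yaml(path)
    if (is.null(overrides)) overrides <- list()
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    overrides <- list()
    for (ln in lines) {
      parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("cannot parse config line: '", ln, "'")
      key <- trimws(parts[1])
      val <- tryCatch(eval(parse(text = trimws(parts[2])), envir = baseenv()),
                      error = function(e) stop("bad value for config key '",
                                               key, "': ", trimws(parts[2])))
      overrides[[key]] <- val
    }
  }
  do.call(default_config, overrides)
}

#' @export
print.mws_config <- function(x, ...) {
  cat("multiwebsim configuration\n")
  cat(sprintf("  web: S = %d, connectance = %g, plants = %d, sessile = %d\n",
              x$S, x$connectance, x$n_plants, x$n_sessile))
  cat(sprintf("  response: q = %g (Hill exponent %g), a0 = %g, h0 = %g\n",
              x$q, 1 + x$q, x$a0, x$h0))
  cat(sprintf("  NTI intensities: c0=%g i0=%g n0=%g p0=%g r0_refuge=%g e0=%g (i0_intra=%g)\n",
              x$c0, x$i0, x$n0, x$p0, x$r0_refuge, x$e0, x$i0_intra))
  cat(sprintf("  solver: t_max = %g, extinction threshold = %g, rtol = %g, atol = %g\n",
              x$t_max, x$ext_threshold, x$rtol, x$atol))
  invisible(x)
}
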