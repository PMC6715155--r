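#' Ordinary least-squares fit of y on x
#'
#' Thin wrapper around [stats::lm()] returning the quantities the ensemble
#' summaries use: slope, intercept, the slope's standard error and the
#' two-sided t-test p-value for a zero slope.
#'
#' @param x,y numeric vectors of equal length, `n >= 2`, `x` not constant.
#' @return an object of class `"regression_fit"`: list with `slope`,
#'   `intercept`, `slope_stderr`, `p_value`, `n`.
#' @export
fit_linear <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stop("fewer than 2 finite (x, y) pairs")
  if (diff(range(x)) == 0) stop("x is constant: slope undefined")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(suppressWarnings(summary(fit)))
  p <- if (nrow(cf) >= 2) cf["x", "Pr(>|t|)"] else NA_real_
  se <- cf["x", "Std. Error"]
  tval <- cf["x", "t value"]
  if (is.nan(p) && is.infinite(tval)) p <- 0   # exact fit, nonzero slope
  structure(list(slope = unname(cf["x", "Estimate"]),
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 slope_stderr = unname(se),
                 p_value = unname(p),
                 n = length(x)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): slope %.6g (se %.3g, p = %.3g), intercept %.6g\n",
              x$n, x$slope, x$slope_stderr, x$p_value, x$intercept))
  invisible(x)
}

#' Test for equal slopes in two groups (ANCOVA)
#'
#' Fits the pooled linear model `y ~ x * group` and returns the two-sided
#' p-value of the interaction term, the classical ANCOVA test that the two
#' group slopes are equal.  Used to compare the diversity-functioning slope
#' with versus without non-trophic interactions.
#'
#' @param x1,y1 first group.
#' @param x2,y2 second group.
#' @return list with `p_value` (interaction), `slope1`, `slope2`,
#'   `slope_diff` and `n`.
#' @export
ancova_slopes <- function(x1, y1, x2, y2) {
  stopifnot(length(x1) == length(y1), length(x2) == length(y2),
            length(x1) >= 3, length(x2) >= 3)
  dat <- data.frame(x = c(x1, x2), y = c(y1, y2),
                    group = factor(rep(c("g1", "g2"),
                                       c(length(x1), length(x2)))))
  dat <- dat[is.finite(dat$x) & is.finite(dat$y), ]
  fit <- stats::lm(y ~ x * group, data = dat)
  cf <- stats::coef(summary(fit))
  if (!"x:groupg2" %in% rownames(cf)) stop("degenerate design: no interaction term")
  list(p_value = unname(cf["x:groupg2", "Pr(>|t|)"]),
       slope1 = unname(cf["x", "Estimate"]),
       slope2 = unname(cf["x", "Estimate"] + cf["x:groupg2", "Estimate"]),
       slope_diff = unname(cf["x:groupg2", "Estimate"]),
       n = nrow(dat))
}

#' Histogram of diversity ratios with per-bin mean intensities
#'
#' Bins the diversity ratios of an ensemble (default bin width 0.01, the
#' natural resolution when diversity counts ~100 species) and reports, per
#' bin, the relative frequency and the mean of each NTI intensity, each
#' normalized to `[0, 1]` over its configured range (0 at the range minimum,
#' 1 at the maximum).
#'
#' @param ratios finite numeric vector of diversity ratios.
#' @param intensities data frame of per-run NTI intensities (one column per
#'   type, rows aligned with `ratios`); may be omitted for a plain histogram.
#' @param ranges named list of `c(min, max)` per intensity column (default:
#'   the calibrated ranges in [default_config()]).
#' @param bin_width histogram bin width.
#' @return data frame with `bin_mid`, `frequency` (summing to 1) and one
#'   `mean_<type>` column per intensity.
#' @export
ratio_histogram <- function(ratios, intensities = NULL,
                            ranges = default_config()$intensity_ranges,
                            bin_width = 0.01) {
  if (length(ratios) == 0L || !all(is.finite(ratios))) {
    stop("ratios must be nonempty and finite")
  }
  bin <- round(ratios / bin_width)
  bins <- sort(unique(bin))
  out <- data.frame(bin_mid = bins * bin_width,
                    frequency = as.numeric(table(factor(bin, levels = bins))) /
                      length(bin))
  if (!is.null(intensities)) {
    stopifnot(nrow(intensities) == length(ratios))
    for (ty in names(intensities)) {
      v <- intensities[[ty]]
      if (ty %in% names(ranges)) {
        rg <- ranges[[ty]]
        v <- (v - rg[1]) / (rg[2] - rg[1])
      }
      out[[paste0("mean_", ty)]] <-
        as.numeric(tapply(v, factor(bin, levels = bins), mean))
    }
  }
  out
}

#' Mean relative change per trophic-level class
#'
#' Aggregates paired per-class metrics (as produced by [compute_metrics()]
#' for the with- and without-NTI arms) into the mean normalized ratio of
#' each variable per trophic-level class.
#'
#' @param per_tl_pairs data frame with columns `class`, `diversity_with`,
#'   `diversity_without`, `biomass_with`, `biomass_without`,
#'   `production_with`, `production_without`, one row per run and class.
#' @return data frame with one row per class and the mean relative change of
#'   diversity, biomass and production (`NA` pairs with a zero baseline are
#'   dropped from the mean).
#' @export
per_tl_summary <- function(per_tl_pairs) {
  need <- c("class", "diversity_with", "diversity_without", "biomass_with",
            "biomass_without", "production_with", "production_without")
  stopifnot(all(need %in% names(per_tl_pairs)))
  cls <- factor(per_tl_pairs$class, levels = unique(per_tl_pairs$class))
  agg <- function(w, wo) {
    r <- normalized_ratio(w, wo)
    as.numeric(tapply(r, cls, mean, na.rm = TRUE))
  }
  data.frame(
    class = levels(cls),
    diversity_change = agg(per_tl_pairs$diversity_with,
                           per_tl_pairs$diversity_without),
    biomass_change = agg(per_tl_pairs$biomass_with,
                         per_tl_pairs$biomass_without),
    production_change = agg(per_tl_pairs$production_with,
                            per_tl_pairs$production_without),
    row.names = NULL)
}
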