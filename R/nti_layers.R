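#' Non-trophic interaction types
#'
#' The six non-trophic interaction (NTI) mechanisms, in the order used for
#' per-type probability and intensity vectors: competition for space,
#' predator interference, increase in mortality, decrease in mortality,
#' refuge provisioning and recruitment facilitation.
#' @export
nti_types <- c("competition", "interference", "mortality_increase",
               "mortality_decrease", "refuge", "recruitment")

#' Eligible species pairs for a non-trophic interaction type
#'
#' Returns the ordered (source, target) pairs on which a link of the given
#' NTI type may be placed, following the qualitative placement rules observed
#' in rocky-shore multiplex networks:
#' \itemize{
#'   \item competition for space: both species sessile (directed: effect of
#'     source on target; competition is asymmetric);
#'   \item interference: two mobile consumers sharing at least one prey
#'     (returned as both orderings; presence is stored symmetrically and
#'     drawn once per unordered pair);
#'   \item refuge provisioning: a sessile species protecting a species that
#'     has at least one consumer;
#'   \item recruitment facilitation: a consumer species facilitating a plant;
#'   \item mortality increase / decrease: any pair of distinct species.
#' }
#' Intraspecific pairs are never eligible.
#'
#' @param web a `"trophic_web"`.
#' @param traits a `"species_traits"`.
#' @param nti_type one of [nti_types].
#' @return integer matrix with columns `source`, `target` (ordered pairs).
#' @export
eligible_pairs <- function(web, traits, nti_type) {
  nti_type <- match.arg(nti_type, nti_types)
  S <- web$S
  adj <- web$adjacency
  diag(adj) <- FALSE
  pair_grid <- function(sources, targets) {
    m <- cbind(source = rep(sources, each = length(targets)),
               target = rep(targets, times = length(sources)))
    m[m[, 1L] != m[, 2L], , drop = FALSE]
  }
  switch(nti_type,
    competition = {
      sess <- which(traits$is_sessile)
      pair_grid(sess, sess)
    },
    interference = {
      mob_cons <- which(!traits$is_sessile & !web$is_plant)
      if (length(mob_cons) < 2L) {
        return(matrix(integer(0), ncol = 2L,
                      dimnames = list(NULL, c("source", "target"))))
      }
      diets <- adj[mob_cons, , drop = FALSE]
      shared <- tcrossprod(diets * 1L) > 0
      idx <- which(upper.tri(shared) & shared, arr.ind = TRUE)
      one_way <- cbind(source = mob_cons[idx[, 1L]],
                       target = mob_cons[idx[, 2L]])
      rbind(one_way, one_way[, c(2L, 1L), drop = FALSE])
    },
    refuge = {
      sess <- which(traits$is_sessile)
      has_consumer <- which(colSums(adj) > 0L)
      pair_grid(sess, has_consumer)
    },
    recruitment = {
      pair_grid(which(!web$is_plant), which(web$is_plant))
    },
    mortality_increase = ,
    mortality_decrease = {
      pair_grid(seq_len(S), seq_len(S))
    })
}

#' Draw one non-trophic interaction layer
#'
#' Places links of one NTI type at random over its eligible pairs: every
#' eligible ordered pair is present independently with probability
#' `probability`, except interference, where one Bernoulli draw per
#' unordered pair is stored symmetrically (the interference weight is
#' symmetric in the two predators).  The realized link count of a layer is
#' the number of nonzero elements of its presence matrix.
#'
#' @param web a `"trophic_web"`.
#' @param traits a `"species_traits"`.
#' @param nti_type one of [nti_types].
#' @param probability per-pair presence probability in `[0, 1]`.
#' @param intensity nonnegative interaction intensity recorded with the layer
#'   (c0, i0, n0, p0, r0_refuge or e0 depending on the type).
#' @return an object of class `"nti_layer"`: list with `nti_type`, `presence`
#'   (S x S logical, `[source, target]`), `probability`, `intensity`,
#'   `n_links`.
#' @export
draw_nti_layer <- function(web, traits, nti_type, probability, intensity = 0) {
  nti_type <- match.arg(nti_type, nti_types)
  stopifnot(probability >= 0, probability <= 1, intensity >= 0)
  S <- web$S
  presence <- matrix(FALSE, S, S)
  pairs <- eligible_pairs(web, traits, nti_type)
  if (nrow(pairs) > 0L) {
    if (nti_type == "interference") {
      half <- pairs[pairs[, 1L] < pairs[, 2L], , drop = FALSE]
      keep <- stats::runif(nrow(half)) < probability
      kept <- half[keep, , drop = FALSE]
      presence[kept] <- TRUE
      presence[kept[, c(2L, 1L), drop = FALSE]] <- TRUE
    } else {
      keep <- stats::runif(nrow(pairs)) < probability
      presence[pairs[keep, , drop = FALSE]] <- TRUE
    }
  }
  structure(list(nti_type = nti_type, presence = presence,
                 probability = probability, intensity = intensity,
                 n_links = sum(presence)),
            class = "nti_layer")
}

#' Assemble a multiplex network
#'
#' Bundles a trophic web, its species traits and a set of NTI layers (at most
#' one per type) into one object.
#'
#' @param web a `"trophic_web"`.
#' @param traits a `"species_traits"`.
#' @param layers list of `"nti_layer"` objects.
#' @return an object of class `"multiplex"`.
#' @export
multiplex_network <- function(web, traits, layers = list()) {
  types <- vapply(layers, function(l) l$nti_type, character(1))
  if (anyDuplicated(types)) stop("at most one layer per NTI type")
  for (l in layers) {
    stopifnot(nrow(l$presence) == web$S)
  }
  names(layers) <- types
  structure(list(web = web, traits = traits, layers = layers),
            class = "multiplex")
}

#' Draw a full set of NTI layers for a web
#'
#' Draws one layer per requested type with per-type probabilities and
#' intensities, returning a `"multiplex"`.
#'
#' @param web a `"trophic_web"`.
#' @param traits a `"species_traits"`.
#' @param probabilities named numeric vector of per-type probabilities
#'   (default: the single-type probabilities in [default_config()]).
#' @param intensities named numeric vector of per-type intensities; types
#'   missing from the vector get intensity 0.
#' @param types which NTI types to draw (default: all six).
#' @return a `"multiplex"`.
#' @export
draw_multiplex <- function(web, traits,
                           probabilities = default_config()$p_nti,
                           intensities = numeric(0),
                           types = nti_types) {
  layers <- lapply(types, function(ty) {
    inten <- if (ty %in% names(intensities)) intensities[[ty]] else 0
    draw_nti_layer(web, traits, ty, probabilities[[ty]], inten)
  })
  multiplex_network(web, traits, layers)
}

#' @export
print.nti_layer <- function(x, ...) {
  cat(sprintf("NTI layer '%s': %d links (p = %g, intensity = %g)\n",
              x$nti_type, x$n_links, x$probability, x$intensity))
  invisible(x)
}

#' @export
print.multiplex <- function(x, ...) {
  print(x$web)
  print(x$traits)
  if (length(x$layers) == 0L) {
    cat("no non-trophic layers\n")
  } else {
    for (l in x$layers) print(l)
  }
  invisible(x)
}
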