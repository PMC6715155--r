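## Serialization: delimited edge lists and species tables, 0-based ids,
## headers required; floats at 12 significant digits.

fmt_num <- function(x) formatC(x, digits = 12, format = "g")

#' Write a multiplex network to a directory
#'
#' Writes `species.csv` (id, is_plant, is_sessile, TL, mass, niche),
#' `trophic_links.csv` (consumer_id, resource_id), `nti_links.csv`
#' (type, source_id, target_id) and `nti_layers.csv` (type, probability,
#' intensity).  Species ids are 0-based integers.
#'
#' @param mx a `"multiplex"`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_multiplex <- function(mx, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  web <- mx$web
  traits <- mx$traits
  species <- data.frame(id = seq_len(web$S) - 1L,
                        is_plant = as.integer(web$is_plant),
                        is_sessile = as.integer(traits$is_sessile),
                        TL = fmt_num(traits$TL),
                        mass = fmt_num(traits$mass),
                        niche = fmt_num(web$niche))
  utils::write.csv(species, file.path(dir, "species.csv"), row.names = FALSE,
                   quote = FALSE)
  links <- which(web$adjacency, arr.ind = TRUE)
  utils::write.csv(data.frame(consumer_id = links[, 1L] - 1L,
                              resource_id = links[, 2L] - 1L),
                   file.path(dir, "trophic_links.csv"), row.names = FALSE,
                   quote = FALSE)
  nti_rows <- lapply(mx$layers, function(l) {
    idx <- which(l$presence, arr.ind = TRUE)
    if (nrow(idx) == 0L) {
      data.frame(type = character(0), source_id = integer(0),
                 target_id = integer(0))
    } else {
      data.frame(type = l$nti_type, source_id = idx[, 1L] - 1L,
                 target_id = idx[, 2L] - 1L)
    }
  })
  utils::write.csv(do.call(rbind, c(nti_rows, list(make.row.names = FALSE))),
                   file.path(dir, "nti_links.csv"), row.names = FALSE,
                   quote = FALSE)
  layer_meta <- data.frame(
    type = vapply(mx$layers, function(l) l$nti_type, character(1)),
    probability = vapply(mx$layers, function(l) l$probability, numeric(1)),
    intensity = vapply(mx$layers, function(l) l$intensity, numeric(1)))
  utils::write.csv(layer_meta, file.path(dir, "nti_layers.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a multiplex network written by [write_multiplex()]
#'
#' @param dir directory containing the csv files.
#' @return a `"multiplex"`.
#' @export
read_multiplex <- function(dir) {
  read_file <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop("missing file: ", path)
    tryCatch(utils::read.csv(path),
             error = function(e) stop("cannot parse ", path, ": ",
                                      conditionMessage(e)))
  }
  species <- read_file("species.csv")
  need <- c("id", "is_plant", "is_sessile", "TL", "mass", "niche")
  if (!all(need %in% names(species))) {
    stop("species.csv must have columns: ", paste(need, collapse = ", "))
  }
  species <- species[order(species$id), ]
  S <- nrow(species)
  links <- read_file("trophic_links.csv")
  adjacency <- matrix(FALSE, S, S)
  adjacency[cbind(links$consumer_id + 1L, links$resource_id + 1L)] <- TRUE
  web <- structure(list(S = S, adjacency = adjacency,
                        is_plant = species$is_plant == 1L,
                        niche = as.numeric(species$niche),
                        n_links = nrow(links)),
                   class = "trophic_web")
  traits <- structure(list(is_sessile = species$is_sessile == 1L,
                           TL = as.numeric(species$TL),
                           mass = as.numeric(species$mass)),
                      class = "species_traits")
  nti_links <- read_file("nti_links.csv")
  layer_meta <- read_file("nti_layers.csv")
  layers <- lapply(seq_len(nrow(layer_meta)), function(k) {
    ty <- layer_meta$type[k]
    presence <- matrix(FALSE, S, S)
    rows <- nti_links[nti_links$type == ty, , drop = FALSE]
    presence[cbind(rows$source_id + 1L, rows$target_id + 1L)] <- TRUE
    structure(list(nti_type = ty, presence = presence,
                   probability = layer_meta$probability[k],
                   intensity = layer_meta$intensity[k],
                   n_links = sum(presence)),
              class = "nti_layer")
  })
  multiplex_network(web, traits, layers)
}

#' Write an ensemble results table
#'
#' Plain CSV with a `# manifest:` comment header carrying the reproducibility
#' metadata (seed, config echo, package version), so a results file is
#' self-describing.
#'
#' @param table data frame of per-run results.
#' @param path output file.
#' @param manifest optional list from [run_manifest()].
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, manifest = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(manifest)) {
    writeLines(paste0("# manifest: ", manifest_string(manifest)), con)
  }
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Read an ensemble results table written by [write_results()]
#'
#' @param path file path.
#' @return data frame; the manifest string (if present) is attached as
#'   attribute `"manifest"`.
#' @export
read_results <- function(path) {
  first <- readLines(path, n = 1L)
  has_manifest <- startsWith(first, "# manifest: ")
  out <- utils::read.csv(path, comment.char = "#")
  if (has_manifest) {
    attr(out, "manifest") <- sub("^# manifest: ", "", first)
  }
  out
}

#' Build a run manifest
#'
#' Captures what is needed to reproduce a pipeline stage: the seed, the full
#' configuration, the package version and free-form stage counters.
#'
#' @param seed integer seed used for the stage.
#' @param config the `"mws_config"` used.
#' @param counts named list/vector of per-stage tallies (rows written,
#'   rejections, ...).
#' @return a list of class `"run_manifest"`.
#' @export
run_manifest <- function(seed, config, counts = list()) {
  structure(list(seed = seed,
                 package_version =
                   as.character(utils::packageVersion("multiwebsim")),
                 config = config,
                 counts = counts),
            class = "run_manifest")
}

manifest_string <- function(m) {
  cfg <- m$config
  flat <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    if (is.list(v)) v <- unlist(v)
    paste0(k, "=", paste(fmt_num(as.numeric(v)), collapse = "|"))
  }, character(1))
  paste(c(paste0("seed=", m$seed),
          paste0("version=", m$package_version),
          flat,
          if (length(m$counts)) {
            paste0(names(m$counts), "=", unlist(m$counts))
          }),
        collapse = "; ")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run manifest (seed ", x$seed, ", multiwebsim ",
      x$package_version, ")\n", sep = "")
  if (length(x$counts)) {
    cat("counts:", paste(names(x$counts), unlist(x$counts), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}
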