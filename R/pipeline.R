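# End-to-end conveniences: one map from curves to statistics, and a
# post-thaw monitoring series over several timepoints.

#' Analyse one force map end to end
#'
#' Fits every curve, applies the QC cascade, builds the stiffness and
#' height maps, partitions the cell by height and computes the timepoint
#' statistics.
#'
#' @param map A [force_map()].
#' @param config A [filter_config()].
#' @param robust Robust (default) or least-squares modulus fitting.
#' @param verbose Print per-stage counts.
#' @return A list: `fits` (table), `stiffness`, `height`, `partition`,
#'   `stats` (one-row data.frame).
#' @export
analyze_force_map <- function(map, config = filter_config(), robust = TRUE,
                              verbose = FALSE) {
  fits <- fit_force_map(map, config = config, robust = robust,
                        verbose = verbose)
  maps <- build_maps(fits)
  part <- partition_regions(maps$height)
  stats <- timepoint_statistics(maps$stiffness, part,
                                time_min = map$timestamp_min)
  list(fits = fits, stiffness = maps$stiffness, height = maps$height,
       partition = part, stats = stats)
}

#' Simulate and analyse a post-thaw monitoring series
#'
#' Generates one phantom force map per timepoint, runs the full pipeline on
#' each, and assembles the per-timepoint statistics and the relative-change
#' profile of the whole-cell median.
#'
#' @param spec A [phantom_spec()].
#' @param times_min Increasing vector of acquisition times, minutes.
#' @param config A [filter_config()].
#' @param robust Robust (default) or least-squares fitting.
#' @param verbose Print progress.
#' @return A list: `stats` (one row per timepoint), `series` (see
#'   [time_series()]) and `analyses` (per-timepoint pipeline outputs).
#' @export
run_post_thaw_series <- function(spec, times_min = seq(0, 120, by = 30),
                                 config = filter_config(), robust = TRUE,
                                 verbose = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"), length(times_min) >= 2L)
  analyses <- vector("list", length(times_min))
  for (i in seq_along(times_min)) {
    if (verbose) message("timepoint ", times_min[i], " min")
    map <- simulate_force_map(spec, time_min = times_min[i])
    analyses[[i]] <- analyze_force_map(map, config = config, robust = robust,
                                       verbose = verbose)
  }
  stats <- do.call(rbind, lapply(analyses, `[[`, "stats"))
  list(stats = stats, series = time_series(stats), analyses = analyses)
}

#' Write maps as delimited-text matrices
#'
#' Exports a stiffness or height map as a tab-separated value matrix
#' (masked-out entries as `NA`) with a small `#%` metadata header.
#'
#' @param map A `stiffness_map` or `height_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_matrix <- function(map, path) {
  stopifnot(!is.null(map$values), !is.null(map$mask))
  vals <- map$values
  vals[!map$mask] <- NA_real_
  kind <- class(map)[1]
  con <- file(path, "wb")
  writeLines(c(sprintf("#%%forcemap-matrix 1"),
               sprintf("#%%kind: %s", kind),
               sprintf("#%%n_rows: %d", nrow(vals)),
               sprintf("#%%n_cols: %d", ncol(vals))), con)
  close(con)
  dt <- data.table::as.data.table(vals)
  data.table::fwrite(.exact_doubles(dt), path, sep = "\t", append = TRUE,
                     col.names = FALSE, nThread = 1L)
  invisible(path)
}

#' Serialise a phantom spec to an editable text file
#'
#' Writes the spec as versioned YAML so simulated studies can be described
#' and re-run from a plain-text document.
#'
#' @param spec A [phantom_spec()].
#' @param path File path.
#' @return `path` invisibly, or the spec.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  doc <- c(list(schema = "phantom-spec-1"), unclass(spec))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$schema, "phantom-spec-1")) {
    stop("not a phantom-spec-1 document: ", path, call. = FALSE)
  }
  doc$schema <- NULL
  doc$decay$tau_min <- as.numeric(doc$decay$tau_min)  # "Inf" round trip
  for (nm in c("extent_um", "cell_center_um")) doc[[nm]] <- as.numeric(doc[[nm]])
  if (!is.null(doc$fibers)) {
    doc$fibers <- lapply(doc$fibers, function(fb) {
      fb$from_um <- as.numeric(fb$from_um)
      fb$to_um <- as.numeric(fb$to_um)
      fb
    })
  }
  do.call(phantom_spec, doc)
}
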