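# Force-map container and the plain-text exchange archive format.
#
# One archive per map: a versioned key-value header (lines starting "#%")
# followed by a single tab-separated table with one row per sample,
# columns (row, col, sample_index, piezo_height_um, deflection_V, segment).
# Doubles are written with 17 significant digits so a write/read cycle is
# bit-exact.

.EXCHANGE_MAGIC <- "#%forcemap-exchange 1"

#' Assemble a force map
#'
#' A rectangular grid of force curves over one field of view, plus the
#' acquisition metadata (probe, calibration, set point, physical extent)
#' shared by all of them. Curves are stored row-major; missing grid points
#' are allowed as `NULL` entries.
#'
#' @param curves List of [force_curve()] objects, row-major, length
#'   `n_rows * n_cols`.
#' @param n_rows,n_cols Grid dimensions (at most 64 each).
#' @param extent_um Physical extent `c(width, height)` in um.
#' @param probe A [probe_geometry()].
#' @param calib A [calibration_record()].
#' @param set_point_nn Relative set point in nN.
#' @param timestamp_min Acquisition time in minutes (e.g. post-thaw).
#' @param seed Generator seed if the map is synthetic, else `NA`.
#' @return An object of class `force_map`.
#' @export
force_map <- function(curves, n_rows, n_cols, extent_um,
                      probe, calib, set_point_nn = 1,
                      timestamp_min = 0, seed = NA_integer_) {
  stopifnot(length(curves) == n_rows * n_cols,
            n_rows >= 1, n_cols >= 1, n_rows <= 64, n_cols <= 64,
            length(extent_um) == 2, all(extent_um > 0),
            inherits(probe, "probe_geometry"),
            inherits(calib, "calibration_record"))
  structure(list(curves = curves, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols),
                 extent_um = as.numeric(extent_um),
                 probe = probe, calib = calib,
                 set_point_nn = set_point_nn,
                 timestamp_min = timestamp_min,
                 seed = seed),
            class = "force_map")
}

#' @export
print.force_map <- function(x, ...) {
  cat(sprintf("<force_map> %d x %d curves over %g x %g um\n",
              x$n_rows, x$n_cols, x$extent_um[1], x$extent_um[2]))
  cat(sprintf("  probe R = %g um, k = %g N/m, sensitivity = %g nm/V, set point %g nN\n",
              x$probe$radius_um, x$calib$spring_constant_n_per_m,
              x$calib$sensitivity_nm_per_v, x$set_point_nn))
  cat(sprintf("  t = %g min%s\n", x$timestamp_min,
              if (!is.na(x$seed)) sprintf(", synthetic (seed %d)", x$seed) else ""))
  invisible(x)
}

.curve_at <- function(map, row, col) {
  map$curves[[(row - 1L) * map$n_cols + col]]
}

.fmt_num <- function(x) sprintf("%.17g", x)

# Render double columns as 17-significant-digit strings in place, so the
# text written by fwrite() parses back to bit-identical doubles.
.exact_doubles <- function(dt) {
  for (nm in names(dt)) {
    if (is.double(dt[[nm]])) {
      data.table::set(dt, j = nm, value = .fmt_num(dt[[nm]]))
    }
  }
  dt
}

#' Write a force map to an exchange archive
#'
#' Serialises the map as a plain-text archive: a `#%`-prefixed key-value
#' header carrying the acquisition metadata, then one tab-separated row per
#' sample. Numeric fields keep 17 significant digits, so
#' [read_force_map()] reproduces the map bit-exactly.
#'
#' @param map A [force_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_force_map <- function(map, path) {
  stopifnot(inherits(map, "force_map"))
  hdr <- c(
    .EXCHANGE_MAGIC,
    sprintf("#%%probe_radius_um: %s", .fmt_num(map$probe$radius_um)),
    sprintf("#%%sensitivity_nm_per_v: %s",
            .fmt_num(map$calib$sensitivity_nm_per_v)),
    sprintf("#%%spring_constant_n_per_m: %s",
            .fmt_num(map$calib$spring_constant_n_per_m)),
    sprintf("#%%temperature_k: %s", .fmt_num(map$calib$temperature_k)),
    sprintf("#%%set_point_nn: %s", .fmt_num(map$set_point_nn)),
    sprintf("#%%n_rows: %d", map$n_rows),
    sprintf("#%%n_cols: %d", map$n_cols),
    sprintf("#%%extent_x_um: %s", .fmt_num(map$extent_um[1])),
    sprintf("#%%extent_y_um: %s", .fmt_num(map$extent_um[2])),
    sprintf("#%%timestamp_min: %s", .fmt_num(map$timestamp_min)),
    sprintf("#%%seed: %s",
            if (is.na(map$seed)) "NA" else as.character(map$seed)))
  con <- file(path, open = "wb")
  writeLines(hdr, con)
  close(con)
  idx <- which(!vapply(map$curves, is.null, logical(1)))
  blocks <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    li <- idx[i]
    cur <- map$curves[[li]]
    r <- ((li - 1L) %/% map$n_cols) + 1L
    cc <- ((li - 1L) %% map$n_cols) + 1L
    blocks[[i]] <- data.table::data.table(
      row = r, col = cc,
      sample_index = seq_along(cur$piezo_height_um),
      piezo_height_um = cur$piezo_height_um,
      deflection_V = cur$deflection,
      segment = cur$segment,
      sample_rate_hz = cur$sample_rate_hz)
  }
  tab <- .exact_doubles(data.table::rbindlist(blocks))
  data.table::fwrite(tab, path, sep = "\t", append = TRUE,
                     col.names = TRUE, nThread = 1L)
  invisible(path)
}

.parse_header <- function(lines) {
  out <- list()
  for (ln in lines) {
    body <- sub("^#%", "", ln)
    pos <- regexpr(": ", body, fixed = TRUE)
    if (pos < 0) next
    key <- substr(body, 1L, pos - 1L)
    out[[key]] <- substr(body, pos + 2L, nchar(body))
  }
  out
}

#' Read a force map from an exchange archive
#'
#' @param path Path to an archive written by [write_force_map()].
#' @return A [force_map()].
#' @export
read_force_map <- function(path) {
  con <- file(path, open = "r")
  first <- readLines(con, n = 1L)
  if (!identical(first, .EXCHANGE_MAGIC)) {
    close(con)
    stop("not a forcemap-exchange v1 archive: ", path, call. = FALSE)
  }
  hdr_lines <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#%")) break
    hdr_lines <- c(hdr_lines, ln)
  }
  close(con)
  h <- .parse_header(hdr_lines)
  need <- c("probe_radius_um", "sensitivity_nm_per_v",
            "spring_constant_n_per_m", "set_point_nn", "n_rows", "n_cols",
            "extent_x_um", "extent_y_um", "timestamp_min")
  miss <- setdiff(need, names(h))
  if (length(miss)) {
    stop("archive header missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab <- data.table::fread(path, sep = "\t", skip = length(hdr_lines) + 1L,
                           header = TRUE, nThread = 1L)
  n_rows <- as.integer(h$n_rows); n_cols <- as.integer(h$n_cols)
  probe <- probe_geometry(radius_um = as.numeric(h$probe_radius_um))
  calib <- calibration_record(
    sensitivity_nm_per_v = as.numeric(h$sensitivity_nm_per_v),
    spring_constant_n_per_m = as.numeric(h$spring_constant_n_per_m),
    temperature_k = if (!is.null(h$temperature_k))
      as.numeric(h$temperature_k) else 310.15)
  curves <- vector("list", n_rows * n_cols)
  lin <- (tab$row - 1L) * n_cols + tab$col
  rows_by_curve <- split(seq_len(nrow(tab)), lin)
  for (key in names(rows_by_curve)) {
    li <- as.integer(key)
    sub <- tab[rows_by_curve[[key]]]
    curves[[li]] <- force_curve(
      piezo_height_um = sub$piezo_height_um,
      deflection = sub$deflection_V,
      deflection_unit = "V",
      segment = sub$segment,
      sample_rate_hz = if ("sample_rate_hz" %in% names(sub))
        sub$sample_rate_hz[1] else 2000,
      grid_index = c(sub$row[1], sub$col[1]))
  }
  force_map(curves, n_rows, n_cols,
            extent_um = c(as.numeric(h$extent_x_um), as.numeric(h$extent_y_um)),
            probe = probe, calib = calib,
            set_point_nn = as.numeric(h$set_point_nn),
            timestamp_min = as.numeric(h$timestamp_min),
            seed = if (is.null(h$seed) || h$seed == "NA") NA_integer_
                   else as.integer(h$seed))
}

#' Fit every curve of a force map
#'
#' Runs contact-point estimation, modulus fitting and the QC cascade on
#' each grid point and collects the results in a flat table (one row per
#' point). Points whose curve fails to fit carry `NA` estimates and the
#' failure message in `error`; they are never silently dropped.
#'
#' @param map A [force_map()].
#' @param config A [filter_config()].
#' @param robust Robust (default) or least-squares modulus estimation.
#' @param poisson_ratio Poisson ratio, default 0.5.
#' @param verbose Print per-stage counts.
#' @return A `data.table` with columns `row`, `col`, `young_modulus_kpa`,
#'   `contact_height_um`, `contact_index`, `max_indentation_um`,
#'   `force_at_deepest_nn`, `rms_residual_nn`, `max_abs_residual_nn`,
#'   `qc_flags` (comma-separated), `accepted`, `error`; attribute
#'   `map_meta` keeps grid shape and metadata.
#' @export
fit_force_map <- function(map, config = filter_config(), robust = TRUE,
                          poisson_ratio = 0.5, verbose = FALSE) {
  stopifnot(inherits(map, "force_map"))
  n <- map$n_rows * map$n_cols
  res <- vector("list", n)
  for (li in seq_len(n)) {
    r <- ((li - 1L) %/% map$n_cols) + 1L
    cc <- ((li - 1L) %% map$n_cols) + 1L
    cur <- map$curves[[li]]
    row_out <- list(row = r, col = cc, young_modulus_kpa = NA_real_,
                    contact_height_um = NA_real_, contact_index = NA_integer_,
                    max_indentation_um = NA_real_,
                    force_at_deepest_nn = NA_real_,
                    rms_residual_nn = NA_real_, max_abs_residual_nn = NA_real_,
                    qc_flags = "", accepted = FALSE, error = "")
    if (is.null(cur)) {
      row_out$error <- "missing curve"
      res[[li]] <- row_out
      next
    }
    fit <- tryCatch({
      cp <- estimate_contact_point(cur, map$calib, map$probe,
                                   poisson_ratio = poisson_ratio)
      f <- fit_young_modulus(cur, map$calib, map$probe, cp$index,
                             robust = robust, poisson_ratio = poisson_ratio,
                             set_point_nn = map$set_point_nn)
      apply_qc_filters(f, config)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      row_out$error <- conditionMessage(fit)
    } else {
      row_out$young_modulus_kpa <- fit$young_modulus_kpa
      row_out$contact_height_um <- fit$contact_point_height_um
      row_out$contact_index <- fit$contact_point_index
      row_out$max_indentation_um <- fit$max_indentation_um
      row_out$force_at_deepest_nn <- fit$force_at_deepest_nn
      row_out$rms_residual_nn <- fit$rms_residual_nn
      row_out$max_abs_residual_nn <- fit$max_abs_residual_nn
      row_out$qc_flags <- paste(fit$qc_flags, collapse = ",")
      row_out$accepted <- fit$accepted
    }
    res[[li]] <- row_out
  }
  out <- data.table::rbindlist(res)
  if (verbose) {
    flg <- out$qc_flags[out$qc_flags != ""]
    message(sprintf("curves in: %d, fitted: %d, accepted: %d", n,
                    sum(out$error == ""), sum(out$accepted)))
    for (rule in c("substrate_stiff", "over_indented", "short_fit",
                   "poor_rms", "poor_maxdev")) {
      message(sprintf("  rejected by %s: %d", rule,
                      sum(grepl(rule, flg, fixed = TRUE))))
    }
  }
  data.table::setattr(out, "map_meta",
                      list(n_rows = map$n_rows, n_cols = map$n_cols,
                           extent_um = map$extent_um,
                           set_point_nn = map$set_point_nn,
                           timestamp_min = map$timestamp_min))
  out
}

#' Write / read a per-curve fits table
#'
#' Tab-separated export of the table produced by [fit_force_map()], with
#' full-precision doubles so the round trip is bit-exact.
#'
#' @param fits The fits table.
#' @param path File path.
#' @return `path` invisibly, or the table.
#' @export
write_fits_table <- function(fits, path) {
  data.table::fwrite(.exact_doubles(data.table::copy(fits)), path,
                     sep = "\t", nThread = 1L)
  invisible(path)
}

#' @rdname write_fits_table
#' @export
read_fits_table <- function(path) {
  data.table::fread(path, sep = "\t", nThread = 1L)
}
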