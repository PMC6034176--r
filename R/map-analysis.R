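# Map-level analysis: assemble per-curve fits into co-registered stiffness
# and height maps, remove the substrate plane, partition the cell by
# height, and compute per-timepoint statistics.

#' Build stiffness and height maps from a fits table
#'
#' Stiffness values come from accepted fits only. Height is the piezo
#' height at contact with a least-squares plane subtracted, so the
#' substrate sits at zero. Substrate points are classified as those
#' carrying the `substrate_stiff` flag or lying within the noise floor of
#' the fitted plane; the plane fit is iterated once after re-classification.
#' With fewer than 3 substrate points the zero level falls back to the
#' global minimum height (with a warning).
#'
#' @param fits Fits table from [fit_force_map()] (or [read_fits_table()]).
#' @param n_rows,n_cols Grid shape; taken from the table's `map_meta`
#'   attribute when omitted.
#' @param noise_floor_um Minimum half-width of the substrate band around
#'   the fitted plane, um.
#' @return A list with elements `stiffness` (class `stiffness_map`) and
#'   `height` (class `height_map`). Both carry `values` and `mask`
#'   matrices; the height map additionally carries `cell_mask`,
#'   `substrate_mask` and the fitted plane parameters.
#' @export
build_maps <- function(fits, n_rows = NULL, n_cols = NULL,
                       noise_floor_um = 0.05) {
  meta <- attr(fits, "map_meta")
  if (is.null(n_rows)) n_rows <- meta$n_rows
  if (is.null(n_cols)) n_cols <- meta$n_cols
  if (is.null(n_rows) || is.null(n_cols)) {
    stop("grid shape unknown; pass n_rows and n_cols", call. = FALSE)
  }
  E <- matrix(NA_real_, n_rows, n_cols)
  z0 <- matrix(NA_real_, n_rows, n_cols)
  acc <- matrix(FALSE, n_rows, n_cols)
  substrate_flag <- matrix(FALSE, n_rows, n_cols)
  ij <- cbind(fits$row, fits$col)
  E[ij] <- fits$young_modulus_kpa
  z0[ij] <- fits$contact_height_um
  acc[ij] <- fits$accepted
  substrate_flag[ij] <- grepl("substrate_stiff", fits$qc_flags, fixed = TRUE)
  valid_z <- is.finite(z0)

  xs <- matrix(rep(seq_len(n_cols), each = n_rows), n_rows, n_cols)
  ys <- matrix(rep(seq_len(n_rows), times = n_cols), n_rows, n_cols)

  fit_plane <- function(sel) {
    df <- data.frame(z = z0[sel], x = xs[sel], y = ys[sel])
    coef(lm(z ~ x + y, data = df))
  }
  sel0 <- substrate_flag & valid_z
  if (sum(sel0) >= 3L) {
    pl <- fit_plane(sel0)
    plane <- pl[1] + pl[2] * xs + pl[3] * ys
    resid <- z0 - plane
    floor_um <- max(noise_floor_um, 3 * mad(resid[sel0]))
    # one re-classification pass: pull in unflagged points sitting on the plane
    sel1 <- valid_z & (substrate_flag | abs(resid) <= floor_um)
    if (sum(sel1) >= 3L) {
      pl <- fit_plane(sel1)
      plane <- pl[1] + pl[2] * xs + pl[3] * ys
      resid <- z0 - plane
      floor_um <- max(noise_floor_um, 3 * mad(resid[sel1]))
    }
    substrate <- valid_z & (substrate_flag | abs(resid) <= floor_um)
  } else {
    warning("fewer than 3 substrate points; using global minimum height ",
            "as the zero level", call. = FALSE)
    plane <- matrix(min(z0[valid_z]), n_rows, n_cols)
    resid <- z0 - plane
    floor_um <- noise_floor_um
    substrate <- valid_z & (substrate_flag | abs(resid) <= floor_um)
  }
  height <- z0 - plane
  cell <- acc & valid_z & !substrate & height > floor_um

  stiffness <- structure(
    list(values = ifelse(acc, E, NA_real_), mask = acc,
         n_rows = n_rows, n_cols = n_cols),
    class = "stiffness_map")
  height_map <- structure(
    list(values = height, mask = valid_z,
         cell_mask = cell, substrate_mask = substrate,
         noise_floor_um = floor_um,
         n_rows = n_rows, n_cols = n_cols),
    class = "height_map")
  list(stiffness = stiffness, height = height_map)
}

#' @export
print.stiffness_map <- function(x, ...) {
  cat(sprintf("<stiffness_map> %d x %d, %d accepted points, median %.3f kPa\n",
              x$n_rows, x$n_cols, sum(x$mask),
              median(x$values[x$mask])))
  invisible(x)
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d, %d cell / %d substrate points, peak %.3f um\n",
              x$n_rows, x$n_cols, sum(x$cell_mask), sum(x$substrate_mask),
              if (any(x$cell_mask)) max(x$values[x$cell_mask]) else NA))
  invisible(x)
}

#' Partition a cell into lower and upper height regions
#'
#' The full cell height is the maximum height over the cell mask. Points at
#' or above half of it form the upper (core/nuclear) region; the remaining
#' cell points form the lower (edge) region. A point exactly at 50 percent
#' belongs to the upper region.
#'
#' @param height A `height_map` from [build_maps()].
#' @return An object of class `region_partition` with logical matrices
#'   `cell_mask`, `substrate_mask`, `lower_region`, `upper_region` and the
#'   scalar `full_height_um`.
#' @export
partition_regions <- function(height) {
  stopifnot(inherits(height, "height_map"))
  cell <- height$cell_mask
  if (!any(cell)) {
    stop("empty cell mask; nothing to partition", call. = FALSE)
  }
  full <- max(height$values[cell])
  upper <- cell & height$values >= 0.5 * full
  lower <- cell & !upper
  structure(list(cell_mask = cell,
                 substrate_mask = height$substrate_mask,
                 lower_region = lower,
                 upper_region = upper,
                 full_height_um = full),
            class = "region_partition")
}

#' Per-timepoint stiffness statistics
#'
#' Median and mean modulus over the cell mask and over the lower/upper
#' regions, the standard error of the mean, a Shapiro-Wilk normality
#' p-value, and the spatial deviation of each region median from the
#' whole-cell median (reported both as |region median - map median| / map
#' median and as MAD/median dispersion).
#'
#' @param stiffness A `stiffness_map`.
#' @param partition A `region_partition` co-registered with it.
#' @param time_min Acquisition time in minutes post thaw.
#' @return A one-row data.frame (`timepoint_stats`).
#' @export
timepoint_statistics <- function(stiffness, partition, time_min = NA_real_) {
  stopifnot(inherits(stiffness, "stiffness_map"),
            inherits(partition, "region_partition"))
  sel <- partition$cell_mask & stiffness$mask
  e <- stiffness$values[sel]
  if (length(e) < 3L) {
    stop("fewer than 3 accepted cell points; statistics undefined",
         call. = FALSE)
  }
  e_lo <- stiffness$values[partition$lower_region & stiffness$mask]
  e_up <- stiffness$values[partition$upper_region & stiffness$mask]
  med <- median(e)
  sw <- if (length(e) >= 3L && length(e) <= 5000L) {
    tryCatch(shapiro.test(e)$p.value, error = function(cnd) NA_real_)
  } else {
    shapiro.test(e[seq_len(5000L)])$p.value
  }
  data.frame(
    time_post_thaw_min = time_min,
    n_points = length(e),
    median_e_kpa = med,
    mean_e_kpa = mean(e),
    sem_kpa = sd(e) / sqrt(length(e)),
    shapiro_p = sw,
    median_e_lower_kpa = if (length(e_lo)) median(e_lo) else NA_real_,
    median_e_upper_kpa = if (length(e_up)) median(e_up) else NA_real_,
    dev_lower = if (length(e_lo)) abs(median(e_lo) - med) / med else NA_real_,
    dev_upper = if (length(e_up)) abs(median(e_up) - med) / med else NA_real_,
    mad_over_median = mad(e) / med)
}

#' Relative-change profile of a post-thaw time series
#'
#' Normalises the per-timepoint whole-cell median to the first timepoint
#' and reports the maximum relative decrease, alongside the per-region
#' deviations already computed per timepoint.
#'
#' @param stats A data.frame of rows from [timepoint_statistics()], ordered
#'   by increasing `time_post_thaw_min`.
#' @return A list with `profile` (the input plus `relative_median`) and
#'   `max_decrease_pct` (percentage decrease of the median from the first
#'   timepoint).
#' @export
time_series <- function(stats) {
  stopifnot(is.data.frame(stats), nrow(stats) >= 2L)
  t <- stats$time_post_thaw_min
  if (any(diff(t) <= 0)) {
    stop("timepoints must be strictly increasing", call. = FALSE)
  }
  rel <- stats$median_e_kpa / stats$median_e_kpa[1]
  out <- stats
  out$relative_median <- rel
  list(profile = out,
       max_decrease_pct = 100 * max(0, 1 - min(rel)))
}
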