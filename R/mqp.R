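#' Extract the failed-pixel set from a gamma map
#'
#' Voxels with gamma strictly greater than 1 fail the criteria; gamma = 1
#' is a pass. Returns the sorted failed values plus masked/failed counts.
#'
#' @param gmap a `gamma_map` from [gamma_map] or [gamma_bruteforce].
#' @return An object of class `failed_gammas` with fields `values` (sorted
#'   ascending), `n_masked`, `n_failed`.
#' @export
failed_gammas <- function(gmap) {
  stopifnot(inherits(gmap, "gamma_map"))
  g <- gmap$gamma[gmap$mask$values]
  if (!length(g)) stop("gamma map has an empty mask")
  f <- sort(g[g > 1])
  structure(list(values = f, n_masked = length(g), n_failed = length(f),
                 cap = gmap$cap),
            class = "failed_gammas")
}

#' @export
print.failed_gammas <- function(x, ...) {
  cat(sprintf("<failed_gammas> %d of %d masked voxels failed (gamma > 1)\n",
              x$n_failed, x$n_masked))
  invisible(x)
}

#' Percentile of the failed-pixel gamma histogram
#'
#' Linear interpolation between closest order statistics: the x-th
#' percentile sits at rank `1 + (n - 1) * x / 100` of the sorted failed
#' values (the convention of [stats::quantile] type 7). An empty failed set
#' returns 1.0, the pass/fail boundary, so that a failure-free comparison
#' contributes a neutral value.
#'
#' @param fs a [failed_gammas] object (or bare numeric vector of gamma
#'   values > 1).
#' @param x percentile in \[0, 100\].
#' @return The gamma value at the x-th percentile (dimensionless).
#' @export
percentile_of_failed <- function(fs, x) {
  if (!is.finite(x) || x < 0 || x > 100)
    stop("'x' must be a percentile in [0, 100]")
  v <- if (inherits(fs, "failed_gammas")) fs$values else as.numeric(fs)
  if (!length(v)) return(1.0)
  unname(stats::quantile(v, probs = x / 100, type = 7, names = FALSE))
}

#' Match quality parameter (MQP)
#'
#' `MQP_x,i = gamma_x,ref - gamma_x,i`: the difference between the x-th
#' failed-percentile gamma of the reference comparison and of the current
#' comparison. Negative values mean the current anatomy match is worse than
#' the reference match.
#'
#' @param gamma_ref_x reference-comparison percentile gamma (>= 0).
#' @param gamma_i_x current-comparison percentile gamma (>= 0).
#' @return The MQP (dimensionless).
#' @export
mqp_value <- function(gamma_ref_x, gamma_i_x) {
  if (any(!is.finite(c(gamma_ref_x, gamma_i_x))) ||
      any(c(gamma_ref_x, gamma_i_x) < 0))
    stop("percentile gamma values must be finite and >= 0")
  gamma_ref_x - gamma_i_x
}

new_mqp_series <- function(segment_id, records, gamma_ref, percentile,
                           criteria, rect_order_fraction = NA,
                           evaluable_reason = NULL) {
  structure(list(segment_id = segment_id, records = records,
                 gamma_ref = gamma_ref, percentile = percentile,
                 criteria = criteria,
                 rect_order_fraction = rect_order_fraction,
                 evaluable_reason = evaluable_reason),
            class = "mqp_series")
}

#' @export
print.mqp_series <- function(x, ...) {
  cat(sprintf("<mqp_series> segment %d, x = %g, criteria (%g mm, %g HU)\n",
              x$segment_id, x$percentile, x$criteria$dta, x$criteria$dhu))
  if (is.null(x$records) || !nrow(x$records))
    cat(sprintf("  non-evaluable: %s\n", x$evaluable_reason %||% "no comparisons"))
  else print(x$records, row.names = FALSE)
  invisible(x)
}

# Build one segment's MQP series from precomputed per-comparison summaries.
# `stats` is a data.frame with columns fraction, n_masked, n_failed, gamma_x
# in acquisition order, the first row being the reference comparison
# (first vs second CBCT of the segment).
series_from_stats <- function(segment_id, stats, percentile, criteria,
                              rect_order_fraction = NA) {
  gamma_ref <- stats$gamma_x[1]
  rec <- data.frame(fraction = stats$fraction, n_masked = stats$n_masked,
                    n_failed = stats$n_failed, gamma_x = stats$gamma_x,
                    mqp = mqp_value(gamma_ref, stats$gamma_x))
  new_mqp_series(segment_id, rec, gamma_ref, percentile, criteria,
                 rect_order_fraction)
}

# Per-comparison failed-pixel summaries for one segment: gamma percentile
# at every x in `x_grid`, plus counts. This is the expensive stage (one
# gamma map per comparison); everything downstream reuses it.
segment_comparison_stats <- function(seg, criteria, x_grid, mask, cap = 5,
                                     saturation_warn = 0.1) {
  n <- length(seg$fractions)
  ref <- segment_volume(seg, 1, grid_ref = mask)
  out <- vector("list", n - 1L)
  for (i in 2:n) {
    ev <- segment_volume(seg, i, grid_ref = mask)
    gm <- gamma_map(ref, ev, criteria, mask, cap = cap)
    fs <- failed_gammas(gm)
    if (fs$n_failed > 0) {
      sat <- mean(fs$values >= cap)
      if (sat > saturation_warn)
        warning(sprintf(
          "segment %d fraction %d: %.0f%% of failed gammas saturate at cap %g",
          seg$segment_id, seg$fractions[i], 100 * sat, cap))
    }
    out[[i - 1L]] <- data.frame(
      fraction = seg$fractions[i], n_masked = fs$n_masked,
      n_failed = fs$n_failed,
      t(vapply(x_grid, function(x) percentile_of_failed(fs, x), 0)))
  }
  st <- do.call(rbind, out)
  names(st)[-(1:3)] <- paste0("x", x_grid)
  st
}

#' Build per-fraction MQP series over a treatment course
#'
#' Within each plan segment the first CBCT is the reference volume; the
#' reference comparison (first vs second CBCT) yields `gamma_x,ref`, and
#' every subsequent CBCT i is compared against the segment's first CBCT to
#' give `gamma_x,i` and `MQP_x,i = gamma_x,ref - gamma_x,i`. The record for
#' the segment's second CBCT therefore has MQP = 0 exactly. Segments are
#' independent: a replan resets the reference. Segments with fewer than two
#' CBCTs cannot form a reference comparison and are returned as
#' non-evaluable (empty records), not an error.
#'
#' @param course a [ct_course].
#' @param criteria a [gamma_criteria].
#' @param x failed-histogram percentile in \[0, 100\] (default 80).
#' @param mask analysis [mask3d]; defaults to
#'   `build_analysis_mask(course$external, course$ctv, margin)`.
#' @param cap gamma cap (default 5).
#' @param margin mask margin in mm used when `mask` is NULL.
#' @return A list of `mqp_series`, one per segment, with per-record columns
#'   `fraction`, `n_masked`, `n_failed`, `gamma_x`, `mqp`.
#' @export
build_mqp_series <- function(course, criteria, x = 80, mask = NULL,
                             cap = 5, margin = 10) {
  stopifnot(inherits(course, "ct_course"), inherits(criteria, "gamma_criteria"))
  if (!is.finite(x) || x < 0 || x > 100) stop("'x' must be in [0, 100]")
  if (is.null(mask)) {
    if (is.null(course$external) || is.null(course$ctv))
      stop("no analysis mask supplied and course carries no external/CTV masks")
    mask <- build_analysis_mask(course$external, course$ctv, margin)
  }
  lapply(course$segments, function(seg) {
    if (length(seg$fractions) < 2L)
      return(new_mqp_series(seg$segment_id, NULL, NA_real_, x, criteria,
                            seg$rect_order_fraction,
                            evaluable_reason = "fewer than 2 CBCTs: no reference comparison"))
    st <- segment_comparison_stats(seg, criteria, x, mask, cap = cap)
    names(st)[4] <- "gamma_x"
    series_from_stats(seg$segment_id, st, x, criteria,
                      seg$rect_order_fraction)
  })
}

#' Export MQP series to CSV
#'
#' One row per comparison: columns `segment`, `fraction`, `n_masked`,
#' `n_failed`, `gamma_x`, `mqp`. Non-evaluable segments contribute no rows.
#'
#' @param series_list list of `mqp_series` (from [build_mqp_series]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_mqp_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    if (is.null(s$records) || !nrow(s$records)) return(NULL)
    cbind(segment = s$segment_id, s$records)
  })
  df <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(df))
    df <- data.frame(segment = integer(), fraction = integer(),
                     n_masked = integer(), n_failed = integer(),
                     gamma_x = numeric(), mqp = numeric())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot an MQP series against fraction number
#'
#' @param x an `mqp_series`.
#' @param threshold optional decision threshold drawn as a dashed line.
#' @param ... passed to [graphics::plot].
#' @return `x`, invisibly.
#' @export
plot.mqp_series <- function(x, threshold = NULL, ...) {
  if (is.null(x$records) || !nrow(x$records)) {
    warning("non-evaluable segment: nothing to plot")
    return(invisible(x))
  }
  graphics::plot(x$records$fraction, x$records$mqp, type = "b", pch = 19,
                 xlab = "Fraction number", ylab = sprintf("MQP (x = %g)", x$percentile),
                 main = sprintf("Segment %d: %g mm / %g HU", x$segment_id,
                                x$criteria$dta, x$criteria$dhu), ...)
  graphics::abline(h = 0, col = "grey60")
  if (!is.null(threshold))
    graphics::abline(h = threshold, lty = 2, col = "red")
  invisible(x)
}
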