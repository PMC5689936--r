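#' Re-CT decision rule configuration
#'
#' The alert fires when `run_length` consecutive acquired comparisons all
#' have MQP at or below `threshold`. Positive thresholds are rejected: the
#' alert must only respond to matches that are worse than the reference.
#'
#' @param threshold MQP decision threshold (dimensionless, < 0).
#' @param run_length consecutive comparisons required (default 3).
#' @param window fraction tolerance for scoring a trigger against the
#'   recorded re-CT order (default 3).
#' @return An object of class `decision_config`.
#' @export
decision_config <- function(threshold, run_length = 3, window = 3) {
  if (!is.finite(threshold) || threshold >= 0)
    stop("'threshold' must be < 0: positive thresholds would alert on matches better than the reference")
  if (run_length < 1) stop("'run_length' must be >= 1")
  if (window < 0) stop("'window' must be >= 0")
  structure(list(threshold = as.numeric(threshold),
                 run_length = as.integer(run_length),
                 window = as.integer(window)),
            class = "decision_config")
}

#' Apply the consecutive-threshold trigger rule to an MQP series
#'
#' Records are scanned in acquisition order (including the segment's
#' zero-valued reference record, which can never satisfy a negative
#' threshold). The trigger fires at the first record completing
#' `run_length` consecutive records with MQP <= threshold. "Consecutive"
#' means consecutive acquired comparisons: gaps in fraction numbering do
#' not break a run; a record with MQP above the threshold does. All
#' fractions at which the run condition is (re-)satisfied are retained in
#' `trigger_fractions`, since with a persistently depressed MQP the
#' condition keeps holding at later records too.
#'
#' @param series an `mqp_series`.
#' @param cfg a [decision_config].
#' @return A `trigger_result`: `triggered` (logical), `trigger_fraction`
#'   (first firing fraction, `NA` if none), `trigger_fractions` (all firing
#'   fractions), `segment_id`.
#' @export
evaluate_trigger <- function(series, cfg) {
  stopifnot(inherits(series, "mqp_series"), inherits(cfg, "decision_config"))
  rec <- series$records
  if (is.null(rec) || !nrow(rec))
    return(structure(list(triggered = FALSE, trigger_fraction = NA_integer_,
                          trigger_fractions = integer(),
                          segment_id = series$segment_id),
                     class = "trigger_result"))
  below <- rec$mqp <= cfg$threshold
  run <- integer(length(below))
  r <- 0L
  for (i in seq_along(below)) {
    r <- if (below[i]) r + 1L else 0L
    run[i] <- r
  }
  hits <- rec$fraction[run >= cfg$run_length]
  structure(list(triggered = length(hits) > 0,
                 trigger_fraction = if (length(hits)) hits[1] else NA_integer_,
                 trigger_fractions = hits,
                 segment_id = series$segment_id),
            class = "trigger_result")
}

#' @export
print.trigger_result <- function(x, ...) {
  if (x$triggered)
    cat(sprintf("<trigger_result> segment %d: ALERT at fraction %d (condition also met at %s)\n",
                x$segment_id, x$trigger_fraction,
                paste(x$trigger_fractions, collapse = ",")))
  else
    cat(sprintf("<trigger_result> segment %d: no alert\n", x$segment_id))
  invisible(x)
}

#' Can a segment be scored under the decision rule?
#'
#' A segment qualifies only if it has at least `run_length` comparisons
#' after (and excluding) the reference comparison; shorter segments cannot
#' satisfy the consecutive condition meaningfully and are excluded from
#' scoring.
#'
#' @param series an `mqp_series`.
#' @param cfg a [decision_config].
#' @return logical(1).
#' @export
is_evaluable <- function(series, cfg) {
  rec <- series$records
  if (is.null(rec)) return(FALSE)
  (nrow(rec) - 1L) >= cfg$run_length
}

#' Classify a segment's outcome against the recorded re-CT order
#'
#' With an order at fraction `f_o`: true positive (TP) if any trigger event
#' lies within `window` fractions of `f_o`; false positive (FP) if the rule
#' fired but only before `f_o - window` (a premature alarm); false negative
#' (FN) if no trigger event occurred at or before `f_o + window` (a miss,
#' including triggers that come only after the window). With no order:
#' FP if the rule fired at all, TN otherwise.
#'
#' @param trigger a `trigger_result` from [evaluate_trigger].
#' @param rect_order_fraction recorded re-CT order fraction, or `NA`.
#' @param cfg a [decision_config].
#' @param evaluable logical; `FALSE` yields the label `"non-evaluable"`.
#' @return One of `"TP"`, `"TN"`, `"FP"`, `"FN"`, `"non-evaluable"`.
#' @export
classify_outcome <- function(trigger, rect_order_fraction, cfg,
                             evaluable = TRUE) {
  if (!evaluable) return("non-evaluable")
  hits <- trigger$trigger_fractions
  if (is.na(rect_order_fraction))
    return(if (length(hits)) "FP" else "TN")
  o <- rect_order_fraction
  w <- cfg$window
  if (any(abs(hits - o) <= w)) return("TP")
  if (any(hits < o - w)) return("FP")
  "FN"
}

#' Score a cohort of outcome labels
#'
#' Non-evaluable segments are excluded from the denominators. Rates with a
#' zero denominator are `NA` (undefined), not 0.
#'
#' @param outcomes character vector of labels from [classify_outcome].
#' @return A `confusion_counts` object: `tp`, `tn`, `fp`, `fn`,
#'   `tpf` = tp/(tp+fn) (sensitivity), `fpf` = fp/(fp+tn)
#'   (1 - specificity), `n_non_evaluable`.
#' @export
score_cohort <- function(outcomes) {
  ok <- c("TP", "TN", "FP", "FN", "non-evaluable")
  if (!all(outcomes %in% ok)) stop("unknown outcome label")
  tp <- sum(outcomes == "TP"); tn <- sum(outcomes == "TN")
  fp <- sum(outcomes == "FP"); fn <- sum(outcomes == "FN")
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 tpf = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 fpf = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
                 n_non_evaluable = sum(outcomes == "non-evaluable")),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  TN %d  FP %d  FN %d  (TPF %s, FPF %s, %d non-evaluable)\n",
              x$tp, x$tn, x$fp, x$fn,
              ifelse(is.na(x$tpf), "undef", sprintf("%.3f", x$tpf)),
              ifelse(is.na(x$fpf), "undef", sprintf("%.3f", x$fpf)),
              x$n_non_evaluable))
  invisible(x)
}

#' The standard MQP threshold sweep grid
#'
#' Exactly the 500 values `-0.001 * k` for k = 1..500, from -0.001 down to
#' -0.5 in steps of -0.001.
#'
#' @return numeric(500), strictly decreasing.
#' @export
threshold_grid <- function() {
  -(1:500) / 1000
}

# Trigger events for every threshold at once: for each record i,
# run_of(i, thr) >= run_length iff the max MQP over the trailing
# run_length records is <= thr, so the set of firing thresholds per record
# is thr <= -trailing_max... computed directly per threshold for clarity.
trigger_fractions_by_threshold <- function(records, thresholds, run_length) {
  n <- nrow(records)
  if (n < run_length) {
    return(lapply(thresholds, function(t) integer()))
  }
  # trailing max of run_length consecutive MQP values ending at each record
  mqp <- records$mqp
  tmax <- rep(NA_real_, n)
  for (i in run_length:n)
    tmax[i] <- max(mqp[(i - run_length + 1L):i])
  lapply(thresholds, function(thr) records$fraction[!is.na(tmax) & tmax <= thr])
}

#' ROC sweep over gamma criteria, percentile, and decision threshold
#'
#' For each (dta, dhu) pair the gamma maps of every comparison in the
#' cohort are computed once (the expensive stage) and reduced to failed
#' -histogram percentiles at every `x` in `percentile_grid`; the threshold
#' sweep then only re-scans the cached MQP series. Emits one row per
#' (dta, dhu, x, threshold) with confusion counts and rates over all
#' evaluable segments.
#'
#' @param cohort list of [ct_course] objects carrying external/CTV masks
#'   (or pass `masks`, a list of analysis [mask3d] parallel to `cohort`).
#' @param dta_grid DTA criteria to sweep (mm).
#' @param dhu_grid HU-difference criteria to sweep (HU).
#' @param percentile_grid failed-histogram percentiles to sweep.
#' @param thresholds MQP thresholds (default [threshold_grid]).
#' @param run_length,window decision-rule parameters (defaults 3 and 3).
#' @param cap gamma cap.
#' @param margin analysis-mask margin (mm).
#' @param masks optional list of prebuilt analysis masks.
#' @param keep_series if `TRUE`, attach the per-course MQP series (by
#'   criteria and percentile) as attribute `"series"` of the result.
#' @return data.frame with columns `dta`, `dhu`, `x`, `threshold`, `tp`,
#'   `tn`, `fp`, `fn`, `tpf`, `fpf`, `n_non_evaluable`.
#' @export
roc_sweep <- function(cohort, dta_grid = c(3, 4, 5, 6, 7),
                      dhu_grid = c(20, 30, 40, 50, 60),
                      percentile_grid = seq(50, 95, by = 5),
                      thresholds = threshold_grid(),
                      run_length = 3, window = 3, cap = 5, margin = 10,
                      masks = NULL, keep_series = FALSE) {
  stopifnot(length(cohort) >= 1)
  if (is.null(masks))
    masks <- lapply(cohort, function(co)
      build_analysis_mask(co$external, co$ctv, margin))
  pairs <- expand.grid(dta = dta_grid, dhu = dhu_grid)
  rows <- list()
  series_store <- list()
  for (p in seq_len(nrow(pairs))) {
    crit <- gamma_criteria(pairs$dta[p], pairs$dhu[p])
    # expensive stage: percentile summaries for every comparison, once
    seg_stats <- list()
    for (ci in seq_along(cohort)) {
      co <- cohort[[ci]]
      for (seg in co$segments) {
        key <- sprintf("%s/%d", co$patient_id, seg$segment_id)
        if (length(seg$fractions) < 2L) {
          seg_stats[[key]] <- list(seg = seg, stats = NULL)
        } else {
          st <- tryCatch(
            segment_comparison_stats(seg, crit, percentile_grid, masks[[ci]],
                                     cap = cap),
            error = function(e) stop(sprintf(
              "course %s segment %d failed: %s", co$patient_id,
              seg$segment_id, conditionMessage(e)), call. = FALSE))
          seg_stats[[key]] <- list(seg = seg, stats = st)
        }
      }
    }
    for (x in percentile_grid) {
      xcol <- paste0("x", x)
      series <- lapply(seg_stats, function(ss) {
        if (is.null(ss$stats))
          return(new_mqp_series(ss$seg$segment_id, NULL, NA_real_, x, crit,
                                ss$seg$rect_order_fraction,
                                "fewer than 2 CBCTs"))
        st <- ss$stats[, c("fraction", "n_masked", "n_failed", xcol)]
        names(st)[4] <- "gamma_x"
        series_from_stats(ss$seg$segment_id, st, x, crit,
                          ss$seg$rect_order_fraction)
      })
      if (keep_series)
        series_store[[sprintf("dta%g_dhu%g_x%g", crit$dta, crit$dhu, x)]] <-
          series
      cfg0 <- decision_config(thresholds[1], run_length, window)
      evaluable <- vapply(series, is_evaluable, TRUE, cfg = cfg0)
      orders <- vapply(series, function(s)
        if (is.null(s$rect_order_fraction)) NA_integer_
        else s$rect_order_fraction, NA_integer_)
      hits_by_thr <- lapply(series, function(s) {
        if (is.null(s$records))
          lapply(thresholds, function(t) integer())
        else
          trigger_fractions_by_threshold(s$records, thresholds, run_length)
      })
      for (ti in seq_along(thresholds)) {
        labels <- vapply(seq_along(series), function(si) {
          if (!evaluable[si]) return("non-evaluable")
          hits <- hits_by_thr[[si]][[ti]]
          o <- orders[si]
          if (is.na(o)) return(if (length(hits)) "FP" else "TN")
          if (any(abs(hits - o) <= window)) return("TP")
          if (any(hits < o - window)) return("FP")
          "FN"
        }, "")
        sc <- score_cohort(labels)
        rows[[length(rows) + 1L]] <- data.frame(
          dta = crit$dta, dhu = crit$dhu, x = x, threshold = thresholds[ti],
          tp = sc$tp, tn = sc$tn, fp = sc$fp, fn = sc$fn,
          tpf = sc$tpf, fpf = sc$fpf, n_non_evaluable = sc$n_non_evaluable)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_series) attr(out, "series") <- series_store
  out
}

#' Select the optimum operating point from a ROC sweep table
#'
#' Maximises the Youden index J = TPF - FPF; ties are broken by higher TPF,
#' then more negative threshold, then smaller DTA, smaller HU criterion,
#' and smaller percentile. Deterministic and invariant to row order.
#'
#' @param table data.frame from [roc_sweep].
#' @return The selected row as a one-row data.frame (class
#'   `parameter_set`).
#' @export
select_optimum <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1)
  ok <- !is.na(table$tpf) & !is.na(table$fpf)
  if (!any(ok)) stop("no rows with defined TPF and FPF")
  t2 <- table[ok, , drop = FALSE]
  j <- t2$tpf - t2$fpf
  ord <- order(-j, -t2$tpf, t2$threshold, t2$dta, t2$dhu, t2$x)
  out <- t2[ord[1], , drop = FALSE]
  out$youden <- j[ord[1]]
  rownames(out) <- NULL
  class(out) <- c("parameter_set", "data.frame")
  out
}
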