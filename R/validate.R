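# Threshold estimation from paired IDA/SWATH acquisitions of standards,
# inclusion/exclusion validation into confusion statistics, and
# fragment-overlap reporting between spectra.

#' Estimate shift thresholds from paired IDA/SWATH observations
#'
#' Given one RT-shift and one width-shift observation per precursor ion
#' matched between an IDA and a SWATH acquisition of the same standards, the
#' acceptance thresholds are \code{k} times the population standard
#' deviation of the pooled shift values, per shift type (default
#' \code{k = 1}).
#'
#' @param observations data.frame with columns compound_id, rt_shift,
#'   width_shift (both dimensionless fractions >= 0).
#' @param k multiplier on the population SD.
#' @return named list(rt_shift_max, width_shift_max).
#' @export
estimate_thresholds <- function(observations, k = 1) {
  obs <- as.data.frame(observations)
  stopifnot(all(c("rt_shift", "width_shift") %in% names(obs)))
  if (nrow(obs) < 2L)
    stop("insufficient data: need at least 2 shift observations")
  if (any(obs$rt_shift < 0 | obs$width_shift < 0))
    stop("shift observations must be >= 0")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- list(rt_shift_max = k * pop_sd(obs$rt_shift),
              width_shift_max = k * pop_sd(obs$width_shift))
  if (out$rt_shift_max == 0 || out$width_shift_max == 0)
    warning("degenerate threshold estimate: zero variance in the shifts")
  out
}

#' Shift observations from a paired IDA/SWATH acquisition
#'
#' For every library precursor detectable in the MS1 of both runs, measures
#' the relative RT and FWHM shift of the SWATH peak against the IDA peak —
#' the calibration input of \code{\link{estimate_thresholds}}.
#'
#' @param ida,swath \code{\link{ms_run}} objects of the same standards.
#' @param library list of dia_entry objects.
#' @param params a \code{\link{filtration_params}} (ppm tolerance is used).
#' @return data.frame(compound_id, adduct, rt_shift, width_shift).
#' @export
shift_observations <- function(ida, swath, library,
                               params = filtration_params()) {
  rows <- list()
  for (entry in library) {
    for (i in seq_len(nrow(entry$precursors))) {
      mz <- entry$precursors$mz[i]
      w <- ppm_window(mz, params$ppm_tol)
      tol <- (w["hi"] - w["lo"]) / 2
      pk_i <- detect_peak(extract_xic(ida, 1L, mz, tol), with_snr = FALSE)
      if (is.null(pk_i)) next
      pk_s <- detect_peak(extract_xic(swath, 1L, mz, tol),
                          expected_rt = pk_i$apex_rt,
                          rt_halfwidth = 3 * pk_i$fwhm, with_snr = FALSE)
      if (is.null(pk_s)) next
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = entry$compound_id, adduct = entry$precursors$adduct[i],
        rt_shift = rt_shift(pk_i$apex_rt, pk_s$apex_rt),
        width_shift = width_shift(pk_i$fwhm, pk_s$fwhm),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(compound_id = character(0), adduct = character(0),
                      rt_shift = numeric(0), width_shift = numeric(0)))
  do.call(rbind, rows)
}

#' Confusion statistics from inclusion/exclusion validation
#'
#' The inclusion list holds compounds known to be present (spiked
#' standards), the exclusion list compounds known to be absent
#' (non-endogenous drugs). Identified compounds in neither list are counted
#' separately as "unlisted" and never enter the confusion matrix.
#'
#' @param identified character vector of identified compound ids.
#' @param inclusion,exclusion disjoint character vectors of compound ids.
#' @return object of class "confusion_metrics": tp, fp, tn, fn, unlisted,
#'   sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), fpr = fp/(tn+fp).
#' @export
evaluate_inclusion_exclusion <- function(identified, inclusion, exclusion) {
  identified <- unique(as.character(identified))
  inclusion <- unique(as.character(inclusion))
  exclusion <- unique(as.character(exclusion))
  if (length(intersect(inclusion, exclusion)))
    stop("inclusion and exclusion lists overlap")
  tp <- length(intersect(identified, inclusion))
  fn <- length(setdiff(inclusion, identified))
  fp <- length(intersect(identified, exclusion))
  tn <- length(setdiff(exclusion, identified))
  unlisted <- length(setdiff(identified, c(inclusion, exclusion)))
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn, unlisted = unlisted,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         fpr = if (tn + fp > 0) fp / (tn + fp) else NA_real_),
    class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<confusion_metrics> TP %d  FP %d  TN %d  FN %d (unlisted %d)\n",
    "  sensitivity %.4f  specificity %.4f  FPR %.4f\n"),
    x$tp, x$fp, x$tn, x$fn, x$unlisted,
    x$sensitivity, x$specificity, x$fpr))
  invisible(x)
}

#' Fragment-overlap report between two fragment lists
#'
#' Greedy nearest-m/z matching within \code{mz_tol}: candidate pairs are
#' sorted by |delta m/z| (ties toward lower m/z) and accepted while both
#' members are unmatched. Reports set sizes, matched count and the fraction
#' of each side recovered in the other.
#'
#' @param set_a,set_b numeric m/z vectors (or data.frames with an mz
#'   column).
#' @param mz_tol matching tolerance in Da (> 0).
#' @return list: n_a, n_b, n_matched, frac_a_in_b, frac_b_in_a, pairs
#'   (data.frame mz_a, mz_b, delta).
#' @export
fragment_overlap_report <- function(set_a, set_b, mz_tol = 0.01) {
  stopifnot(mz_tol > 0)
  mz_a <- if (is.data.frame(set_a)) set_a$mz else as.numeric(set_a)
  mz_b <- if (is.data.frame(set_b)) set_b$mz else as.numeric(set_b)
  pairs <- expand.grid(i = seq_along(mz_a), j = seq_along(mz_b))
  pairs$delta <- abs(mz_a[pairs$i] - mz_b[pairs$j])
  pairs <- pairs[pairs$delta <= mz_tol, , drop = FALSE]
  pairs <- pairs[order(pairs$delta, pmin(mz_a[pairs$i], mz_b[pairs$j])), ,
                 drop = FALSE]
  used_a <- logical(length(mz_a)); used_b <- logical(length(mz_b))
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (!used_a[i] && !used_b[j]) {
      keep[r] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  matched <- pairs[keep, , drop = FALSE]
  list(
    n_a = length(mz_a), n_b = length(mz_b), n_matched = nrow(matched),
    frac_a_in_b = if (length(mz_a)) nrow(matched) / length(mz_a) else NA_real_,
    frac_b_in_a = if (length(mz_b)) nrow(matched) / length(mz_b) else NA_real_,
    pairs = data.frame(mz_a = mz_a[matched$i], mz_b = mz_b[matched$j],
                       delta = matched$delta))
}
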