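# Step 2: candidate precursor screening. Every library precursor (per
# adduct) is extracted from MS1 at ppm tolerance in sample and blank and
# gated on S/N and the sample:blank height ratio.

#' Pipeline filtration parameters
#'
#' Defaults are the published operating point of the workflow: 10 ppm
#' precursor tolerance, XIC S/N > 30 and sample:blank > 5 at screening
#' (strict), blank ratio >= 5 at filtration (inclusive), 0.05 Da fragment
#' extraction window, relative RT shift < 0.1417% and relative FWHM shift
#' < 17.4965% between each fragment and its precursor, 5% relative-intensity
#' floor, 75% main-daughter threshold and 0.01 Da de-duplication tolerance.
#'
#' The FWHM-shift threshold is quoted without a unit at its source; by
#' default it is read as a percentage of the parent width (fraction
#' 0.174965). \code{width_shift_literal = TRUE} instead applies the raw
#' number 17.4965 as a fraction, which effectively disables that gate.
#'
#' @param ppm_tol precursor mass tolerance, ppm.
#' @param snr_min minimum precursor XIC S/N (strict >).
#' @param screen_blank_ratio_min sample:blank gate at screening (strict >).
#' @param filter_blank_ratio_min blank-ratio gate at fragment filtration
#'   (inclusive >=).
#' @param frag_tol_da fragment XIC extraction half-window, Da.
#' @param rt_shift_max maximum relative RT shift (fraction).
#' @param width_shift_max maximum relative FWHM shift (fraction).
#' @param width_shift_literal apply the unscaled legacy threshold (see
#'   Details).
#' @param rel_int_min_pct relative-intensity floor, percent.
#' @param d_threshold_pct main-daughter threshold, percent.
#' @param dedup_mz_tol near-duplicate fragment tolerance, Da.
#' @param fragment_blank_gate also blank-gate fragment XICs (not only
#'   precursors).
#' @param score_weights named weights (coverage, rt, cosine) of the
#'   identification score; must sum to 1.
#' @return object of class "filtration_params".
#' @export
filtration_params <- function(ppm_tol = 10, snr_min = 30,
                              screen_blank_ratio_min = 5,
                              filter_blank_ratio_min = 5,
                              frag_tol_da = 0.05,
                              rt_shift_max = 0.001417,
                              width_shift_max = 0.174965,
                              width_shift_literal = FALSE,
                              rel_int_min_pct = 5, d_threshold_pct = 75,
                              dedup_mz_tol = 0.01,
                              fragment_blank_gate = TRUE,
                              score_weights = c(coverage = 0.5, rt = 0.3,
                                                cosine = 0.2)) {
  if (width_shift_literal) width_shift_max <- 17.4965
  p <- list(ppm_tol = ppm_tol, snr_min = snr_min,
            screen_blank_ratio_min = screen_blank_ratio_min,
            filter_blank_ratio_min = filter_blank_ratio_min,
            frag_tol_da = frag_tol_da, rt_shift_max = rt_shift_max,
            width_shift_max = width_shift_max,
            width_shift_literal = width_shift_literal,
            rel_int_min_pct = rel_int_min_pct,
            d_threshold_pct = d_threshold_pct,
            dedup_mz_tol = dedup_mz_tol,
            fragment_blank_gate = fragment_blank_gate,
            score_weights = score_weights)
  num <- unlist(p[c("ppm_tol", "snr_min", "screen_blank_ratio_min",
                    "filter_blank_ratio_min", "frag_tol_da", "rt_shift_max",
                    "width_shift_max", "rel_int_min_pct", "d_threshold_pct",
                    "dedup_mz_tol")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all filtration thresholds must be positive and finite")
  if (abs(sum(score_weights) - 1) > 1e-9)
    stop("score_weights must sum to 1")
  structure(p, class = "filtration_params")
}

#' @export
print.filtration_params <- function(x, ...) {
  cat("<filtration_params>\n")
  for (f in setdiff(names(x), "score_weights"))
    cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  cat(sprintf("  %-24s %s\n", "score_weights",
              paste(sprintf("%s=%.2f", names(x$score_weights),
                            x$score_weights), collapse = " ")))
  invisible(x)
}

.observed_mz <- function(run, scan, lo, hi) {
  sl <- scan_slice(run, scan, lo, hi)
  if (nrow(sl) == 0L || sum(sl$intensity) <= 0) return(NA_real_)
  sum(sl$mz * sl$intensity) / sum(sl$intensity)
}

#' Screen a SWATH run for candidate precursors
#'
#' For every (library entry, adduct) pair the precursor is extracted from
#' MS1 in sample and blank at ppm tolerance; a candidate is kept when a peak
#' is found with S/N above \code{snr_min} and a sample:blank height ratio
#' above \code{screen_blank_ratio_min} (strict). The observed m/z is the
#' intensity-weighted mean of the apex scan's centroids inside the
#' extraction window. Each passing pair yields exactly one candidate.
#'
#' @param sample,blank \code{\link{ms_run}} objects of the same polarity;
#'   \code{blank = NULL} disables the blank gate (ratio +Inf) with a
#'   warning.
#' @param library list of \code{dia_entry} objects.
#' @param params a \code{\link{filtration_params}}.
#' @return data.frame of candidates (class "candidate_table"): compound_id,
#'   splash_id, adduct, library_mz, observed_mz, ppm_error, window_index,
#'   apex_rt, height, fwhm, snr, blank_ratio.
#' @export
screen_precursors <- function(sample, blank, library,
                              params = filtration_params()) {
  stopifnot(inherits(sample, "ms_run"))
  if (!is.null(blank)) {
    if (!inherits(blank, "ms_run")) stop("blank must be an ms_run or NULL")
    if (blank$polarity != sample$polarity)
      stop("sample and blank polarity differ")
  } else {
    warning("no blank run given: blank ratios set to +Inf")
  }
  if (!length(library)) return(.empty_candidates())
  rows <- list()
  for (entry in library) {
    if (entry$polarity != sample$polarity) next
    for (i in seq_len(nrow(entry$precursors))) {
      mz <- entry$precursors$mz[i]
      w <- ppm_window(mz, params$ppm_tol)
      tol <- (w["hi"] - w["lo"]) / 2
      xic <- extract_xic(sample, 1L, mz, tol)
      pk <- detect_peak(xic)
      if (is.null(pk)) next
      if (!(pk$snr > params$snr_min)) next
      bpk <- NULL
      if (!is.null(blank)) {
        bxic <- extract_xic(blank, 1L, mz, tol)
        bpk <- detect_peak(bxic, expected_rt = pk$apex_rt,
                           rt_halfwidth = 3 * pk$fwhm, with_snr = FALSE)
      }
      ratio <- height_ratio(pk, bpk)
      if (!(ratio > params$screen_blank_ratio_min)) next
      apex_scan <- attr(xic, "scan")[pk$apex_index]
      omz <- .observed_mz(sample, apex_scan, w["lo"], w["hi"])
      ppm_err <- if (is.na(omz)) NA_real_ else (omz - mz) / mz * 1e6
      if (!is.na(ppm_err) && abs(ppm_err) > params$ppm_tol) next
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = entry$compound_id, splash_id = entry$splash_id,
        adduct = entry$precursors$adduct[i], library_mz = mz,
        observed_mz = omz, ppm_error = ppm_err,
        window_index = entry$precursors$window_index[i],
        apex_rt = pk$apex_rt, height = pk$height, fwhm = pk$fwhm,
        snr = pk$snr, blank_ratio = ratio, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else .empty_candidates()
  out <- out[order(out$compound_id, out$adduct), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

.empty_candidates <- function() {
  structure(
    data.frame(compound_id = character(0), splash_id = character(0),
               adduct = character(0), library_mz = numeric(0),
               observed_mz = numeric(0), ppm_error = numeric(0),
               window_index = integer(0), apex_rt = numeric(0),
               height = numeric(0), fwhm = numeric(0), snr = numeric(0),
               blank_ratio = numeric(0), stringsAsFactors = FALSE),
    class = c("candidate_table", "data.frame"))
}
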