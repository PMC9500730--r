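# Steps 3-4: fragment XIC alignment to the candidate precursor inside its
# SWATH window, threshold filtration, scoring, and redundancy resolution.
#
# The two co-elution criteria are relative shifts against the parent peak:
#   rt_shift    = |parent RT   - fragment RT|   / parent RT
#   width_shift = |parent FWHM - fragment FWHM| / parent FWHM
# Both are dimensionless fractions; a fragment survives when both fall
# below their configured maxima.

#' Relative retention-time shift between parent and fragment
#'
#' @param parent_rt parent apex RT, minutes (> 0).
#' @param fragment_rt fragment apex RT, minutes.
#' @return dimensionless fraction |parent - fragment| / parent.
#' @export
rt_shift <- function(parent_rt, fragment_rt) {
  if (any(parent_rt <= 0)) stop("parent RT must be > 0")
  abs(parent_rt - fragment_rt) / parent_rt
}

#' Relative peak-width (FWHM) shift between parent and fragment
#'
#' @param parent_fwhm parent FWHM, minutes (> 0).
#' @param fragment_fwhm fragment FWHM, minutes.
#' @return dimensionless fraction |parent - fragment| / parent.
#' @export
width_shift <- function(parent_fwhm, fragment_fwhm) {
  if (any(parent_fwhm <= 0)) stop("parent FWHM must be > 0")
  abs(parent_fwhm - fragment_fwhm) / parent_fwhm
}

#' Align library fragments to a candidate precursor
#'
#' For each curated library fragment of the entry, extracts the MS2 XIC
#' (absolute tolerance \code{frag_tol_da}) in the candidate's SWATH window,
#' looks for a peak near the candidate apex (within +/- 3 parent FWHM) and
#' computes the RT and width shifts plus, when a blank run is supplied, the
#' fragment's sample:blank height ratio. Fragments with no detectable peak
#' carry NA measurements and can never be retained.
#'
#' @param candidate one row of a \code{\link{screen_precursors}} table.
#' @param run the sample \code{\link{ms_run}}.
#' @param entry the candidate's \code{dia_entry}.
#' @param params a \code{\link{filtration_params}}.
#' @param blank optional blank \code{\link{ms_run}}.
#' @return data.frame of aligned fragments (one row per library fragment):
#'   library_mz, tag, library_relative_intensity, found, apex_rt, height,
#'   fwhm, snr, rt_shift, width_shift, blank_ratio,
#'   observed_relative_intensity (filled by \code{\link{apply_filtration}}),
#'   retained.
#' @export
align_fragments <- function(candidate, run, entry,
                            params = filtration_params(), blank = NULL) {
  candidate <- as.list(candidate)
  widx <- candidate$window_index
  if (is.null(run$scheme) || widx < 0L || widx >= n_windows(run$scheme))
    stop("candidate window_index not present in the run's SWATH scheme")
  frag <- entry$fragments
  n <- nrow(frag)
  out <- data.frame(
    library_mz = frag$mz, tag = frag$tag,
    library_relative_intensity = frag$relative_intensity,
    found = FALSE, apex_rt = NA_real_, height = NA_real_, fwhm = NA_real_,
    snr = NA_real_, rt_shift = NA_real_, width_shift = NA_real_,
    blank_ratio = Inf, observed_relative_intensity = NA_real_,
    retained = FALSE, window_index = widx, stringsAsFactors = FALSE)
  halfwidth <- 3 * candidate$fwhm
  for (i in seq_len(n)) {
    if (frag$mz[i] < run$scheme$start || frag$mz[i] > run$scheme$end) next
    xic <- extract_xic(run, 2L, frag$mz[i], params$frag_tol_da, widx)
    pk <- detect_peak(xic, expected_rt = candidate$apex_rt,
                      rt_halfwidth = halfwidth)
    if (is.null(pk)) next
    out$found[i] <- TRUE
    out$apex_rt[i] <- pk$apex_rt
    out$height[i] <- pk$height
    out$fwhm[i] <- pk$fwhm
    out$snr[i] <- pk$snr
    out$rt_shift[i] <- rt_shift(candidate$apex_rt, pk$apex_rt)
    out$width_shift[i] <- width_shift(candidate$fwhm, pk$fwhm)
    if (!is.null(blank) && params$fragment_blank_gate) {
      bxic <- extract_xic(blank, 2L, frag$mz[i], params$frag_tol_da, widx)
      bpk <- detect_peak(bxic, expected_rt = pk$apex_rt,
                         rt_halfwidth = halfwidth, with_snr = FALSE)
      out$blank_ratio[i] <- height_ratio(pk, bpk)
    }
  }
  out
}

#' Filter aligned fragments
#'
#' Two-pass filtration: first the co-elution gates (peak present, blank
#' ratio >= \code{filter_blank_ratio_min}, rt_shift < \code{rt_shift_max},
#' width_shift < \code{width_shift_max}); then relative intensities are
#' recomputed over the gate-passing fragments only (tallest = 100) and
#' fragments below \code{rel_int_min_pct} are dropped. Using only
#' shift-passing fragments as the base-peak reference keeps a
#' background-dominated tall XIC from distorting the scale.
#'
#' @param fragments an \code{\link{align_fragments}} table.
#' @param params a \code{\link{filtration_params}}.
#' @return the table with observed_relative_intensity and retained filled.
#' @export
apply_filtration <- function(fragments, params = filtration_params()) {
  f <- fragments
  pass <- f$found &
    !is.na(f$rt_shift) & f$rt_shift < params$rt_shift_max &
    !is.na(f$width_shift) & f$width_shift < params$width_shift_max &
    f$blank_ratio >= params$filter_blank_ratio_min
  f$observed_relative_intensity <- NA_real_
  if (any(pass)) {
    base <- max(f$height[pass])
    f$observed_relative_intensity[pass] <- 100 * f$height[pass] / base
  }
  f$retained <- pass & !is.na(f$observed_relative_intensity) &
    f$observed_relative_intensity >= params$rel_int_min_pct
  f
}

#' Score an identification
#'
#' Deterministic composite in [0, 1]:
#' \deqn{w_c \frac{\sum_{retained} L_i}{\sum_{all} L_i}
#'   + w_r \left(1 - \overline{rt\_shift / rt\_shift\_max}\right)
#'   + w_s \cos(O, L)}
#' where L are library relative intensities, O the observed relative
#' intensities over retained fragments, and the weights (default
#' 0.5 / 0.3 / 0.2) come from \code{params$score_weights}.
#'
#' @param fragments a filtered \code{\link{apply_filtration}} table.
#' @param params a \code{\link{filtration_params}}.
#' @return numeric score in [0, 1], or NA when nothing is retained.
#' @export
score_identification <- function(fragments, params = filtration_params()) {
  ret <- fragments[fragments$retained, , drop = FALSE]
  if (nrow(ret) == 0L) return(NA_real_)
  w <- params$score_weights
  coverage <- sum(ret$library_relative_intensity) /
    sum(fragments$library_relative_intensity)
  rt_term <- 1 - mean(pmin(ret$rt_shift / params$rt_shift_max, 1))
  o <- ret$observed_relative_intensity
  l <- ret$library_relative_intensity
  cosine <- sum(o * l) / sqrt(sum(o^2) * sum(l^2))
  unname(w["coverage"] * coverage + w["rt"] * rt_term + w["cosine"] * cosine)
}

.make_identification <- function(candidate, fragments, entry, params) {
  ret <- fragments[fragments$retained, , drop = FALSE]
  if (nrow(ret) == 0L || !any(ret$tag == "D")) return(NULL)
  structure(
    list(compound_id = entry$compound_id, splash_id = entry$splash_id,
         compound_name = entry$compound_name,
         adducts = candidate$adduct, candidate = as.list(candidate),
         fragments = fragments, has_D = TRUE,
         score = score_identification(fragments, params)),
    class = "identification")
}

#' @export
print.identification <- function(x, ...) {
  cat(sprintf("<identification> %s [%s] score %.3f, %d/%d fragments retained\n",
              x$compound_name, paste(x$adducts, collapse = ", "), x$score,
              sum(x$fragments$retained), nrow(x$fragments)))
  invisible(x)
}

#' Resolve redundancy across identifications
#'
#' Two rules: (1) multiple adducts of the same compound merge into one
#' identification listing all adducts (the fragment evidence of the adduct
#' with the smallest precursor |ppm error| is kept; ties to the higher
#' score); (2) when identifications of different compounds claim the same
#' fragment XIC (|delta m/z| <= \code{dedup_mz_tol}, same SWATH window, apex
#' RTs within \code{rt_shift_max} of each other in relative terms), the
#' fragment is kept only for the identification with the smaller precursor
#' |ppm error| (tie: higher score). Identifications left without retained
#' fragments or without a retained main daughter are dropped, and scores
#' are recomputed.
#'
#' @param identifications list of identification objects.
#' @param params a \code{\link{filtration_params}}.
#' @return list of identification objects, sorted by compound_id.
#' @export
dedup_redundant <- function(identifications, params = filtration_params()) {
  ids <- identifications
  if (!length(ids)) return(ids)
  # (1) merge adducts per compound
  keyfun <- function(id) id$compound_id
  groups <- split(seq_along(ids), vapply(ids, keyfun, character(1)))
  merged <- lapply(groups, function(idx) {
    if (length(idx) == 1L) return(ids[[idx]])
    err <- vapply(idx, function(i) abs(ids[[i]]$candidate$ppm_error), numeric(1))
    sc <- vapply(idx, function(i) ids[[i]]$score, numeric(1))
    best <- idx[order(err, -sc)][1]
    out <- ids[[best]]
    out$adducts <- sort(unique(unlist(lapply(ids[idx], `[[`, "adducts"))))
    out
  })
  merged <- unname(merged)
  # (2) cross-compound shared-fragment resolution
  n <- length(merged)
  if (n > 1L) {
    prio <- order(vapply(merged, function(x) abs(x$candidate$ppm_error),
                         numeric(1)),
                  -vapply(merged, `[[`, numeric(1), "score"))
    rank <- integer(n); rank[prio] <- seq_len(n)
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      fa <- merged[[a]]$fragments; fb <- merged[[b]]$fragments
      ra <- which(fa$retained); rb <- which(fb$retained)
      if (!length(ra) || !length(rb)) next
      for (i in ra) for (j in rb) {
        if (fa$window_index[i] != fb$window_index[j]) next
        if (abs(fa$library_mz[i] - fb$library_mz[j]) > params$dedup_mz_tol) next
        drt <- abs(fa$apex_rt[i] - fb$apex_rt[j]) /
          max(fa$apex_rt[i], fb$apex_rt[j])
        if (drt > params$rt_shift_max) next
        loser <- if (rank[a] < rank[b]) b else a
        k <- if (loser == a) i else j
        merged[[loser]]$fragments$retained[k] <- FALSE
      }
    }
  }
  out <- list()
  for (id in merged) {
    ret <- id$fragments[id$fragments$retained, , drop = FALSE]
    if (nrow(ret) == 0L || !any(ret$tag == "D")) next
    # rescale observed relative intensities over the surviving set
    base <- max(ret$height)
    id$fragments$observed_relative_intensity <-
      ifelse(id$fragments$retained,
             100 * id$fragments$height / base, NA_real_)
    id$score <- score_identification(id$fragments, params)
    out[[length(out) + 1L]] <- id
  }
  out[order(vapply(out, `[[`, character(1), "compound_id"))]
}

#' Annotate a SWATH run against a DIA library
#'
#' Full pipeline composition: precursor screening, fragment alignment,
#' filtration, scoring, redundancy resolution — deterministic given inputs.
#'
#' @param sample,blank \code{\link{ms_run}} objects (blank may be NULL).
#' @param library list of \code{dia_entry} objects.
#' @param params a \code{\link{filtration_params}}.
#' @return list of identification objects (class "identification_set") with
#'   the candidate table attached as attribute "candidates".
#' @export
annotate_run <- function(sample, blank, library,
                         params = filtration_params()) {
  cands <- screen_precursors(sample, blank, library, params)
  by_splash <- stats::setNames(library,
                               vapply(library, `[[`, character(1), "splash_id"))
  ids <- list()
  for (i in seq_len(nrow(cands))) {
    cand <- cands[i, ]
    entry <- by_splash[[cand$splash_id]]
    aligned <- align_fragments(cand, sample, entry, params, blank)
    filtered <- apply_filtration(aligned, params)
    id <- .make_identification(cand, filtered, entry, params)
    if (!is.null(id)) ids[[length(ids) + 1L]] <- id
  }
  out <- dedup_redundant(ids, params)
  structure(out, candidates = cands, class = "identification_set")
}

#' @export
print.identification_set <- function(x, ...) {
  cat(sprintf("<identification_set> %d identification(s)\n", length(x)))
  for (id in x) print(id)
  invisible(x)
}

#' Flatten identifications to tables
#'
#' \code{identifications_table} gives one row per identification;
#' \code{fragments_table} one row per aligned library fragment. Both are
#' stable-sorted by (compound_id, adduct) so repeated runs diff cleanly.
#'
#' @param ids an \code{\link{annotate_run}} result (or list of
#'   identifications).
#' @return data.frame.
#' @export
identifications_table <- function(ids) {
  if (!length(ids))
    return(data.frame(compound_id = character(0), splash_id = character(0),
                      compound_name = character(0), adducts = character(0),
                      precursor_mz = numeric(0), ppm_error = numeric(0),
                      apex_rt = numeric(0), height = numeric(0),
                      fwhm = numeric(0), snr = numeric(0),
                      n_fragments_retained = integer(0),
                      n_fragments_library = integer(0), score = numeric(0)))
  tab <- do.call(rbind, lapply(ids, function(id) data.frame(
    compound_id = id$compound_id, splash_id = id$splash_id,
    compound_name = id$compound_name,
    adducts = paste(id$adducts, collapse = ";"),
    precursor_mz = id$candidate$library_mz,
    ppm_error = id$candidate$ppm_error, apex_rt = id$candidate$apex_rt,
    height = id$candidate$height, fwhm = id$candidate$fwhm,
    snr = id$candidate$snr,
    n_fragments_retained = sum(id$fragments$retained),
    n_fragments_library = nrow(id$fragments), score = id$score,
    stringsAsFactors = FALSE)))
  tab <- tab[order(tab$compound_id, tab$adducts), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' @rdname identifications_table
#' @export
fragments_table <- function(ids) {
  if (!length(ids)) return(data.frame())
  tab <- do.call(rbind, lapply(ids, function(id) {
    f <- id$fragments
    f$compound_id <- id$compound_id
    f$splash_id <- id$splash_id
    f[, c("compound_id", "splash_id", "library_mz", "tag",
          "library_relative_intensity", "found", "apex_rt", "height", "fwhm",
          "snr", "rt_shift", "width_shift", "blank_ratio",
          "observed_relative_intensity", "retained")]
  }))
  tab <- tab[order(tab$compound_id, tab$library_mz), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
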