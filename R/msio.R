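# Centroided LC-MS run container and mzML I/O (via mzR / proteowizard).
#
# A run is stored column-wise for fast XIC extraction: one table of scan
# metadata and one flat peak table sorted by m/z, so an extraction is a
# binary search over the global m/z ladder followed by a per-scan rollup.
# Retention times are minutes end-to-end; mzML's seconds are converted at
# the file boundary.

#' Construct an in-memory LC-MS run
#'
#' @param scans data.frame with columns ms_level (1 or 2), rt (minutes) and,
#'   for MS2 rows, window_lo / window_hi (Da). Rows must be time-ordered
#'   (non-decreasing rt).
#' @param peaks data.frame with columns scan (row index into \code{scans}),
#'   mz (Da) and intensity (counts).
#' @param scheme optional \code{\link{swath_scheme}}; inferred from the MS2
#'   isolation windows when absent.
#' @param polarity "positive" or "negative".
#' @return object of class "ms_run".
#' @export
ms_run <- function(scans, peaks, scheme = NULL, polarity = "positive") {
  scans <- as.data.frame(scans)
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("ms_level", "rt") %in% names(scans)),
            all(c("scan", "mz", "intensity") %in% names(peaks)))
  if (is.unsorted(scans$rt)) stop("scan retention times must be non-decreasing")
  if (any(scans$rt < 0)) stop("negative retention time")
  if (nrow(peaks) && (min(peaks$scan) < 1L || max(peaks$scan) > nrow(scans)))
    stop("peak table references a scan outside the scan table")
  is_ms2 <- scans$ms_level == 2L
  if (any(is_ms2)) {
    if (!all(c("window_lo", "window_hi") %in% names(scans)) ||
        anyNA(scans$window_lo[is_ms2]) || anyNA(scans$window_hi[is_ms2]))
      stop("MS2 scans must carry isolation-window metadata (window_lo/window_hi)")
    if (is.null(scheme)) scheme <- .infer_scheme(scans[is_ms2, ])
    scans$window_index <- NA_integer_
    centers <- (scans$window_lo[is_ms2] + scans$window_hi[is_ms2]) / 2
    scans$window_index[is_ms2] <- assign_window(centers, scheme)
  } else {
    scans$window_index <- rep(NA_integer_, nrow(scans))
    if (!"window_lo" %in% names(scans))
      scans$window_lo <- rep(NA_real_, nrow(scans))
    if (!"window_hi" %in% names(scans))
      scans$window_hi <- rep(NA_real_, nrow(scans))
  }
  ord <- order(peaks$mz)
  structure(
    list(scans = scans,
         pk_mz = peaks$mz[ord], pk_int = peaks$intensity[ord],
         pk_scan = as.integer(peaks$scan[ord]),
         scheme = scheme, polarity = polarity),
    class = "ms_run"
  )
}

.infer_scheme <- function(ms2_scans) {
  wins <- unique(data.frame(lo = ms2_scans$window_lo, hi = ms2_scans$window_hi))
  widths <- wins$hi - wins$lo
  width <- as.numeric(names(sort(table(signif(widths, 10)),
                                 decreasing = TRUE))[1])
  swath_scheme(start = min(wins$lo), end = max(wins$hi), width = width)
}

#' @export
print.ms_run <- function(x, ...) {
  n1 <- sum(x$scans$ms_level == 1L); n2 <- sum(x$scans$ms_level == 2L)
  cat(sprintf("<ms_run> %d scans (%d MS1, %d MS2), %d centroids, %s mode\n",
              nrow(x$scans), n1, n2, length(x$pk_mz), x$polarity))
  if (!is.null(x$scheme)) print(x$scheme)
  invisible(x)
}

n_scans <- function(run) nrow(run$scans)

#' Read a centroided (SWATH) mzML file
#'
#' The SWATH window scheme is inferred from the set of MS2 isolation windows
#' when MS2 scans are present. Profile-mode spectra are rejected; MS2 scans
#' without isolation-window metadata are a format error.
#'
#' @param path mzML file.
#' @return an \code{\link{ms_run}}.
#' @export
read_ms_run <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fh <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("format error reading mzML: ",
                                          conditionMessage(e), call. = FALSE))
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  if (nrow(hdr) == 0L)
    return(ms_run(data.frame(ms_level = integer(0), rt = numeric(0)),
                  data.frame(scan = integer(0), mz = numeric(0),
                             intensity = numeric(0))))
  if (any(!is.na(hdr$centroided) & !hdr$centroided))
    stop("unsupported data: profile-mode spectra (centroid first)")
  is_ms2 <- hdr$msLevel == 2L
  if (any(is_ms2 & (is.na(hdr$isolationWindowTargetMZ) |
                    is.na(hdr$isolationWindowLowerOffset))))
    stop("format error: MS2 scan(s) missing isolation-window metadata")
  scans <- data.frame(
    ms_level = hdr$msLevel,
    rt = hdr$retentionTime / 60,
    window_lo = hdr$isolationWindowTargetMZ - hdr$isolationWindowLowerOffset,
    window_hi = hdr$isolationWindowTargetMZ + hdr$isolationWindowUpperOffset)
  scans$window_lo[!is_ms2] <- NA_real_
  scans$window_hi[!is_ms2] <- NA_real_
  pks <- mzR::peaks(fh)
  if (is.matrix(pks)) pks <- list(pks)
  npts <- vapply(pks, nrow, integer(1))
  peaks <- data.frame(
    scan = rep.int(seq_along(pks), npts),
    mz = unlist(lapply(pks, function(p) p[, 1]), use.names = FALSE),
    intensity = unlist(lapply(pks, function(p) p[, 2]), use.names = FALSE))
  pol <- if (!is.null(hdr$polarity) && any(hdr$polarity < 0, na.rm = TRUE))
    "negative" else "positive"
  ms_run(scans, peaks, polarity = pol)
}

#' Write a run to mzML
#'
#' Emits standard indexed mzML readable by \code{\link{read_ms_run}};
#' rt / m/z / intensity round-trip losslessly to float precision.
#'
#' @param run an \code{\link{ms_run}}.
#' @param path output file.
#' @return path, invisibly.
#' @export
write_ms_run <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  n <- n_scans(run)
  if (n == 0L) {  # header-only mzML; mzR needs >= 1 spectrum to write
    writeLines(c(
      '<?xml version="1.0" encoding="utf-8"?>',
      '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
      '  <cvList count="2">',
      '    <cv id="MS" fullName="PSI-MS" version="4.1.0" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
      '    <cv id="UO" fullName="Unit Ontology" version="09:04:2014" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
      '  </cvList>',
      '  <fileDescription>',
      '    <fileContent>',
      '      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
      '    </fileContent>',
      '  </fileDescription>',
      '  <softwareList count="1">',
      '    <software id="sw" version="0.1.0">',
      '      <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="swathAnnotator"/>',
      '    </software>',
      '  </softwareList>',
      '  <instrumentConfigurationList count="1">',
      '    <instrumentConfiguration id="IC">',
      '      <cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
      '    </instrumentConfiguration>',
      '  </instrumentConfigurationList>',
      '  <dataProcessingList count="1">',
      '    <dataProcessing id="dp">',
      '      <processingMethod order="0" softwareRef="sw">',
      '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
      '      </processingMethod>',
      '    </dataProcessing>',
      '  </dataProcessingList>',
      '  <run id="empty" defaultInstrumentConfigurationRef="IC">',
      '    <spectrumList count="0" defaultDataProcessingRef="dp">',
      '    </spectrumList>',
      '  </run>',
      '</mzML>'), path)
    return(invisible(path))
  }
  sc <- run$scans
  is_ms2 <- sc$ms_level == 2L
  # per-scan peak lists from the m/z-sorted flat table
  ord <- order(run$pk_scan, run$pk_mz)
  by_scan <- split(ord, factor(run$pk_scan[ord], levels = seq_len(n)))
  pks <- lapply(by_scan, function(idx)
    cbind(mz = run$pk_mz[idx], intensity = run$pk_int[idx]))
  npts <- vapply(pks, nrow, integer(1))
  tic <- vapply(pks, function(p) if (nrow(p)) sum(p[, 2]) else 0, numeric(1))
  bp <- t(vapply(pks, function(p) {
    if (!nrow(p)) return(c(0, 0))
    i <- which.max(p[, 2]); c(p[i, 1], p[i, 2])
  }, numeric(2)))
  lohi <- t(vapply(pks, function(p) {
    if (!nrow(p)) return(c(0, 0)); range(p[, 1])
  }, numeric(2)))
  target <- ifelse(is_ms2, (sc$window_lo + sc$window_hi) / 2, NA_real_)
  off <- ifelse(is_ms2, (sc$window_hi - sc$window_lo) / 2, NA_real_)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = as.integer(sc$ms_level),
    polarity = if (run$polarity == "positive") 1L else 0L,
    peaksCount = npts, totIonCurrent = tic,
    retentionTime = sc$rt * 60,
    basePeakMZ = bp[, 1], basePeakIntensity = bp[, 2],
    collisionEnergy = ifelse(is_ms2, 35, 0),
    ionisationEnergy = 0, lowMZ = lohi[, 1], highMZ = lohi[, 2],
    precursorScanNum = 0L,
    precursorMZ = ifelse(is_ms2, target, 0),
    precursorCharge = ifelse(is_ms2, 1L, 0L), precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = target,
    isolationWindowLowerOffset = off, isolationWindowUpperOffset = off,
    scanWindowLowerLimit = if (is.null(run$scheme)) 50 else run$scheme$start,
    scanWindowUpperLimit = if (is.null(run$scheme)) 1100 else run$scheme$end,
    stringsAsFactors = FALSE)
  mzR::writeMSData(unname(pks), file = path, header = hdr)
  invisible(path)
}

#' Extract an ion chromatogram
#'
#' Sums, per qualifying scan, the centroid intensities within
#' \code{target_mz +/- tol}. For \code{ms_level = 2} the extraction is
#' restricted to MS2 scans of one SWATH isolation window
#' (\code{window_index}, 0-based); scans of other windows never contribute.
#' Every qualifying scan yields one point (zero when nothing matched).
#'
#' @param run an \code{\link{ms_run}}.
#' @param ms_level 1 or 2.
#' @param target_mz centre m/z in Da.
#' @param tol absolute half-window in Da (> 0).
#' @param window_index required iff \code{ms_level = 2}.
#' @return object of class "xic": data.frame(rt, intensity) with attributes
#'   target_mz, tol, ms_level, window_index and scan (contributing scan ids).
#' @export
extract_xic <- function(run, ms_level, target_mz, tol, window_index = NULL) {
  stopifnot(inherits(run, "ms_run"), tol > 0, ms_level %in% c(1L, 2L))
  if (ms_level == 2L) {
    if (is.null(window_index)) stop("window_index is required for MS2 extraction")
    if (is.null(run$scheme) ||
        window_index < 0L || window_index >= n_windows(run$scheme))
      stop("window_index not in the run's SWATH scheme")
    scan_sel <- which(run$scans$ms_level == 2L &
                      run$scans$window_index == window_index)
  } else {
    if (!is.null(window_index)) stop("window_index only applies to MS2 extraction")
    scan_sel <- which(run$scans$ms_level == 1L)
  }
  lo <- target_mz - tol; hi <- target_mz + tol
  i1 <- findInterval(lo, run$pk_mz, left.open = TRUE) + 1L
  i2 <- findInterval(hi, run$pk_mz)
  intensity <- numeric(length(scan_sel))
  if (i2 >= i1 && length(scan_sel)) {
    idx <- i1:i2
    pos <- match(run$pk_scan[idx], scan_sel)
    ok <- !is.na(pos)
    if (any(ok)) {
      sums <- rowsum(run$pk_int[idx][ok], pos[ok])
      intensity[as.integer(rownames(sums))] <- sums[, 1]
    }
  }
  structure(
    data.frame(rt = run$scans$rt[scan_sel], intensity = intensity),
    target_mz = target_mz, tol = tol, ms_level = ms_level,
    window_index = if (ms_level == 2L) window_index else NA_integer_,
    scan = scan_sel,
    class = c("xic", "data.frame")
  )
}

#' Centroids of one scan within an m/z window
#'
#' Used to compute the observed (intensity-weighted) m/z at a peak apex.
#' @param run an \code{\link{ms_run}}.
#' @param scan scan index.
#' @param lo,hi m/z bounds in Da.
#' @return data.frame(mz, intensity).
#' @keywords internal
scan_slice <- function(run, scan, lo, hi) {
  i1 <- findInterval(lo, run$pk_mz, left.open = TRUE) + 1L
  i2 <- findInterval(hi, run$pk_mz)
  if (i2 < i1) return(data.frame(mz = numeric(0), intensity = numeric(0)))
  idx <- (i1:i2)[run$pk_scan[i1:i2] == scan]
  data.frame(mz = run$pk_mz[idx], intensity = run$pk_int[idx])
}
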