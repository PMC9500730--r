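# Chromatographic peak measurement on an XIC: apex RT, raw height, FWHM,
# S/N, sample:blank height ratio. Detection smooths with a 5-point moving
# median followed by a 5-point moving mean (robust to single-scan spikes);
# the reported height is the raw intensity at the apex, and the half-height
# crossings are interpolated on the raw trace so smoothing never widens the
# measured FWHM.

.smooth_trace <- function(x) {
  n <- length(x)
  if (n < 5L) return(x)
  med <- stats::runmed(x, k = 5L, endrule = "median")
  sm <- stats::filter(med, rep(1 / 5, 5), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- med[is.na(sm)]
  sm
}

.noise_floor <- function(x) {
  med <- stats::median(x)
  mad_e <- 1.4826 * stats::median(abs(x - med))
  med + 3 * mad_e
}

.refine_apex <- function(rt, x, apex) {
  # Sub-scan apex localisation and height. A Gaussian peak is exactly
  # quadratic in log-intensity, so a least-squares parabola on log(x) over
  # the contiguous points >= 30% of the apex gives an unbiased vertex (RT)
  # and vertex value (height) while averaging down point noise; with fewer
  # than 4 usable points, fall back to a 3-point parabola on the raw trace
  # (vertex confined to half a sampling interval) and the raw apex sample.
  n <- length(x); h <- x[apex]
  ok <- x > 0 & x >= 0.3 * h
  lo <- apex; while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- apex; while (hi < n && ok[hi + 1L]) hi <- hi + 1L
  idx <- lo:hi
  if (length(idx) >= 4L) {
    t0 <- rt[idx] - rt[apex]
    fit <- stats::lm.fit(cbind(1, t0, t0^2), log(x[idx]))
    cf <- unname(fit$coefficients)
    a <- cf[3]; b <- cf[2]
    if (is.finite(a) && a < 0) {
      v <- -b / (2 * a)
      if (v >= min(t0) && v <= max(t0)) {
        hv <- exp(cf[1] - b^2 / (4 * a))
        if (!is.finite(hv) || hv < 0.5 * h || hv > 2 * h) hv <- h
        return(list(rt = rt[apex] + v, height = hv))
      }
    }
  }
  if (apex > 1L && apex < n) {
    y0 <- x[apex - 1L]; y1 <- x[apex]; y2 <- x[apex + 1L]
    den <- y0 - 2 * y1 + y2
    if (den < 0) {
      d <- 0.5 * (y0 - y2) / den
      d <- max(min(d, 0.5), -0.5)
      return(list(rt = rt[apex] + d * (rt[min(apex + 1L, n)] - rt[apex]),
                  height = h))
    }
  }
  list(rt = rt[apex], height = h)
}

.half_crossing <- function(rt, x, apex, half, step) {
  # walk outward from apex until the raw trace drops below half, then
  # interpolate the crossing; NA when the trace never drops (edge peak)
  i <- apex
  repeat {
    j <- i + step
    if (j < 1L || j > length(x)) return(NA_real_)
    if (x[j] < half) {
      frac <- (x[i] - half) / (x[i] - x[j])
      return(rt[i] + frac * (rt[j] - rt[i]))
    }
    i <- j
  }
}

#' Detect the chromatographic peak in an XIC
#'
#' Finds the apex on a lightly smoothed trace (5-point moving median then
#' 5-point moving mean), optionally restricted to
#' \code{expected_rt +/- rt_halfwidth}; when several local maxima qualify,
#' the one nearest \code{expected_rt} wins (ties to the taller). Returns
#' \code{NULL} when no smoothed point exceeds the noise floor
#' (median + 3 robust SD of the trace).
#'
#' Apex RT and height come from a least-squares parabola on the
#' log-intensities of the contiguous points above 30% of the apex sample —
#' exact for a Gaussian peak (whose log is quadratic) and averaging down
#' single-point noise; when fewer than 4 points are usable the raw apex
#' sample is reported and the RT is localised by a 3-point parabola. FWHM
#' comes from linear interpolation of the raw trace's half-height
#' crossings; if one side never crosses (edge peak) the width is twice the
#' available half-width and the feature is flagged
#' (\code{fwhm_flag = TRUE}). Peaks spanning fewer than 3 consecutive
#' nonzero scans are not reported (an isolated spike is not a
#' chromatographic peak).
#'
#' @param xic an \code{\link{extract_xic}} result (>= 5 points).
#' @param expected_rt optional apex prior, minutes.
#' @param rt_halfwidth half-width of the search window around
#'   \code{expected_rt}, minutes (default: unrestricted).
#' @param with_snr also estimate S/N via \code{\link{estimate_snr}}.
#' @return object of class "peak_feature" (fields apex_rt, height, fwhm,
#'   snr, area, apex_index, fwhm_flag) or \code{NULL} when nothing is found.
#' @export
detect_peak <- function(xic, expected_rt = NULL, rt_halfwidth = NULL,
                        with_snr = TRUE) {
  rt <- xic$rt; x <- xic$intensity
  if (length(x) < 5L) stop("insufficient data: XIC has fewer than 5 points")
  if (max(x) <= 0) return(NULL)
  sm <- .smooth_trace(x)
  floor_ <- .noise_floor(x)
  if (max(sm) <= floor_ && max(x) <= floor_) return(NULL)
  n <- length(x)
  is_max <- sm >= c(-Inf, sm[-n]) & sm >= c(sm[-1], -Inf) & sm > floor_
  cand <- which(is_max)
  if (!length(cand)) cand <- which.max(sm)
  if (!is.null(expected_rt)) {
    if (!is.null(rt_halfwidth))
      cand <- cand[abs(rt[cand] - expected_rt) <= rt_halfwidth]
    if (!length(cand)) return(NULL)
    d <- abs(rt[cand] - expected_rt)
    best <- cand[d == min(d)]
    apex_s <- best[which.max(sm[best])]
  } else {
    apex_s <- cand[which.max(sm[cand])]
  }
  # refine on the raw trace in the smoothed apex's neighbourhood
  nb <- max(1L, apex_s - 2L):min(n, apex_s + 2L)
  apex <- nb[which.max(x[nb])]
  if (x[apex] <= 0) return(NULL)
  # a chromatographic peak must span at least 3 consecutive sampled points;
  # an isolated spike (single nonzero scan) is not a peak
  span <- 1L
  i <- apex; while (i > 1L && x[i - 1L] > 0) { span <- span + 1L; i <- i - 1L }
  i <- apex; while (i < n && x[i + 1L] > 0) { span <- span + 1L; i <- i + 1L }
  if (span < 3L) return(NULL)
  ref <- .refine_apex(rt, x, apex)
  height <- ref$height
  half <- height / 2
  left <- .half_crossing(rt, x, apex, half, -1L)
  right <- .half_crossing(rt, x, apex, half, +1L)
  flag <- is.na(left) || is.na(right)
  fwhm <- if (!is.na(left) && !is.na(right)) right - left
          else if (!is.na(right)) 2 * (right - rt[apex])
          else if (!is.na(left)) 2 * (rt[apex] - left)
          else return(NULL)
  if (fwhm <= 0) return(NULL)
  region <- rt >= rt[apex] - 2 * fwhm & rt <= rt[apex] + 2 * fwhm
  area <- if (sum(region) >= 2L) {
    rr <- rt[region]; xx <- x[region]
    sum(diff(rr) * (xx[-length(xx)] + xx[-1]) / 2)
  } else 0
  pk <- structure(
    list(apex_rt = ref$rt, height = height, fwhm = fwhm,
         snr = NA_real_, area = area, apex_index = apex, fwhm_flag = flag),
    class = "peak_feature")
  if (with_snr) pk$snr <- estimate_snr(xic, pk)
  pk
}

#' @export
print.peak_feature <- function(x, ...) {
  cat(sprintf(
    "<peak> apex %.4f min, height %.4g, FWHM %.4f min, S/N %.3g%s\n",
    x$apex_rt, x$height, x$fwhm, x$snr,
    if (isTRUE(x$fwhm_flag)) " [edge]" else ""))
  invisible(x)
}

#' Signal-to-noise ratio of a detected peak
#'
#' Noise is 1.4826 x the median absolute deviation of the XIC intensities
#' outside \code{apex +/- 2 FWHM}, floored at 1 count; S/N is raw peak
#' height over that noise.
#'
#' @param xic the XIC the peak was detected on.
#' @param peak a \code{\link{detect_peak}} result.
#' @return dimensionless ratio.
#' @export
estimate_snr <- function(xic, peak) {
  stopifnot(inherits(peak, "peak_feature"))
  out <- abs(xic$rt - peak$apex_rt) > 2 * peak$fwhm
  noise <- if (sum(out) >= 3L) {
    v <- xic$intensity[out]
    1.4826 * stats::median(abs(v - stats::median(v)))
  } else 0
  peak$height / max(noise, 1)
}

#' Sample-to-blank peak-height ratio
#'
#' An absent blank peak means the signal is sample-specific; by convention
#' the ratio is then +Inf (passes any threshold).
#'
#' @param sample_peak \code{\link{detect_peak}} result for the sample
#'   (must be present).
#' @param blank_peak corresponding blank peak, or NULL when none detected.
#' @return height ratio.
#' @export
height_ratio <- function(sample_peak, blank_peak) {
  if (is.null(sample_peak)) stop("sample peak must be present")
  if (is.null(blank_peak)) return(Inf)
  sample_peak$height / blank_peak$height
}
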