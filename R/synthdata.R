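# Ground-truthed synthetic spectral libraries and SWATH/IDA runs.
#
# The simulator emulates the acquisition geometry of a quadrupole-TOF SWATH
# experiment: each cycle holds one MS1 survey scan over the full range
# followed by one MS2 scan per fixed isolation window. Compounds elute as
# Gaussian profiles; fragment traces co-elute with their precursor up to a
# configurable multiplicative RT and width jitter; intensities carry
# shot-noise (Gaussian with sd = max(baseline_sd, sqrt(intensity))) and
# every scan receives a set of random background centroids.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

#' Generate a synthetic spectral library
#'
#' Random compounds with neutral monoisotopic masses in (150, 900) Da and
#' fragments strictly below the protonated (or deprotonated) precursor m/z.
#' Relative intensities span the main-daughter (> 75%), secondary (5-75%)
#' and excluded (< 5%) bands: each spectrum gets a base peak at 100%, and
#' each further fragment falls below the 5% cutoff with probability
#' \code{frac_below_cutoff}. Both the raw (pre-curation) spectra and the
#' curated DIA entries are returned so curation itself is testable.
#'
#' @param n_compounds number of compounds (>= 1).
#' @param fragments_per_compound inclusive range of fragment counts drawn
#'   per compound.
#' @param seed RNG seed; identical seeds give identical libraries.
#' @param polarity "positive" or "negative".
#' @param scheme a \code{\link{swath_scheme}}.
#' @param frac_below_cutoff probability a non-base fragment lands below the
#'   5% relative-intensity band.
#' @return list(raw = list of \code{\link{library_spectrum}},
#'   entries = list of dia_entry, rejections = data.frame).
#' @export
make_synthetic_library <- function(n_compounds, fragments_per_compound = c(4, 9),
                                   seed = 1L, polarity = "positive",
                                   scheme = swath_scheme(),
                                   frac_below_cutoff = 0.2) {
  stopifnot(n_compounds >= 1)
  .with_seed(seed, {
    raw <- vector("list", n_compounds)
    for (i in seq_len(n_compounds)) {
      mass <- stats::runif(1, 150, 900)
      prec <- mass + if (polarity == "positive") 1.00728 else -1.00728
      nf <- sample(seq(fragments_per_compound[1], fragments_per_compound[2]), 1)
      frag_mz <- sort(stats::runif(nf, scheme$start + 5, prec - 5))
      rel <- numeric(nf)
      rel[1] <- 100
      if (nf > 1) {
        below <- stats::runif(nf - 1) < frac_below_cutoff
        rel[-1] <- ifelse(below, stats::runif(nf - 1, 0.5, 4.5),
                          stats::runif(nf - 1, 6, 98))
      }
      rel <- rel[sample.int(nf)]                      # base peak anywhere
      base_counts <- stats::runif(1, 1e4, 1e6)
      raw[[i]] <- library_spectrum(
        splash_id = sprintf("splash-syn-%04d", i),
        compound_id = sprintf("SYN%04d", i),
        compound_name = sprintf("synthetic compound %d", i),
        neutral_mass = mass, polarity = polarity,
        fragments = data.frame(mz = frag_mz,
                               intensity = base_counts * rel / 100))
    }
    cur <- curate_library(raw, scheme = scheme)
    list(raw = raw, entries = cur$entries, rejections = cur$rejections)
  })
}

#' Define the ground truth for a simulated pair of runs
#'
#' Picks \code{n_spike} library compounds to be present in the sample, with
#' random apex RTs and precursor heights; optionally \code{n_background}
#' further compounds present at matching height in both sample and blank
#' (matrix background, removed downstream by the blank-ratio gate).
#' Per-fragment apex RTs, widths and heights (including their jitters) are
#' drawn here and frozen in the truth object, so a run regenerated from the
#' same truth is bit-identical.
#'
#' @param entries curated library (list of dia_entry).
#' @param n_spike number of spiked compounds.
#' @param seed RNG seed; also used by \code{\link{simulate_run}} for noise.
#' @param adducts adduct names to spike per compound (those present in the
#'   entry's precursor table are used).
#' @param height_range precursor apex height range, counts (log-uniform).
#' @param rt_range apex RT range, minutes.
#' @param peak_sigma Gaussian elution sigma, minutes.
#' @param rt_jitter_sd fragment RT jitter, SD as a fraction of the RT.
#' @param width_jitter_sd fragment width jitter, SD as a fraction of sigma.
#' @param response_jitter_sdlog lognormal SD of the fragment response
#'   around the library relative intensity.
#' @param mass_error_ppm_sd per-scan m/z error, ppm.
#' @param baseline_sd noise floor of the shot-noise model, counts.
#' @param n_noise_peaks random background centroids per scan.
#' @param noise_mean mean background centroid intensity, counts.
#' @param n_background compounds present in sample AND blank.
#' @param run_rt run start/end, minutes.
#' @param cycle_time SWATH cycle length, minutes.
#' @return object of class "ground_truth".
#' @export
make_ground_truth <- function(entries, n_spike, seed = 1L,
                              adducts = NULL,
                              height_range = c(1e4, 1e5),
                              rt_range = c(1, 4), peak_sigma = 0.05,
                              rt_jitter_sd = 5e-4, width_jitter_sd = 0.05,
                              response_jitter_sdlog = 0.05,
                              mass_error_ppm_sd = 2,
                              baseline_sd = 5, n_noise_peaks = 15,
                              noise_mean = 30, n_background = 0,
                              run_rt = c(0, 5), cycle_time = 0.01) {
  stopifnot(n_spike >= 0, n_spike + n_background <= length(entries))
  polarity <- entries[[1]]$polarity
  if (is.null(adducts))
    adducts <- if (polarity == "positive") "[M+H]+" else "[M-H]-"
  .with_seed(seed, {
    pick <- sample.int(length(entries), n_spike + n_background)
    spiked <- entries[pick[seq_len(n_spike)]]
    background <- if (n_background)
      entries[pick[n_spike + seq_len(n_background)]] else list()
    draw <- function(ents, in_blank) {
      comp <- list(); frag <- list()
      for (e in ents) {
        apex <- stats::runif(1, rt_range[1], rt_range[2])
        h <- exp(stats::runif(1, log(height_range[1]), log(height_range[2])))
        prows <- e$precursors[e$precursors$adduct %in% adducts, , drop = FALSE]
        if (!nrow(prows)) next
        for (p in seq_len(nrow(prows))) {
          comp[[length(comp) + 1L]] <- data.frame(
            compound_id = e$compound_id, splash_id = e$splash_id,
            adduct = prows$adduct[p], precursor_mz = prows$mz[p],
            window_index = prows$window_index[p], apex_rt = apex,
            height = h, sigma = peak_sigma, in_blank = in_blank,
            stringsAsFactors = FALSE)
          nf <- nrow(e$fragments)
          frag[[length(frag) + 1L]] <- data.frame(
            splash_id = e$splash_id, adduct = prows$adduct[p],
            window_index = prows$window_index[p],
            mz = e$fragments$mz,
            tag = e$fragments$tag,
            height = h * (e$fragments$relative_intensity / 100) *
              stats::rlnorm(nf, 0, response_jitter_sdlog),
            apex_rt = apex * (1 + stats::rnorm(nf, 0, rt_jitter_sd)),
            sigma = peak_sigma * (1 + stats::rnorm(nf, 0, width_jitter_sd)),
            in_blank = in_blank, stringsAsFactors = FALSE)
        }
      }
      list(comp = comp, frag = frag)
    }
    s <- draw(spiked, FALSE)
    b <- draw(background, TRUE)
    empty_comp <- data.frame(compound_id = character(0), splash_id = character(0),
                             adduct = character(0), precursor_mz = numeric(0),
                             window_index = integer(0), apex_rt = numeric(0),
                             height = numeric(0), sigma = numeric(0),
                             in_blank = logical(0))
    structure(
      list(seed = seed, polarity = polarity,
           scheme = list(start = 50, end = 1100, width = 50),
           run_rt = run_rt, cycle_time = cycle_time,
           peak_sigma = peak_sigma, rt_jitter_sd = rt_jitter_sd,
           width_jitter_sd = width_jitter_sd,
           mass_error_ppm_sd = mass_error_ppm_sd,
           noise = list(baseline_sd = baseline_sd,
                        n_noise_peaks = n_noise_peaks,
                        noise_mean = noise_mean),
           compounds = if (length(c(s$comp, b$comp)))
             do.call(rbind, c(s$comp, b$comp)) else empty_comp,
           fragments = if (length(c(s$frag, b$frag)))
             do.call(rbind, c(s$frag, b$frag)) else
             data.frame(splash_id = character(0), adduct = character(0),
                        window_index = integer(0), mz = numeric(0),
                        tag = character(0), height = numeric(0),
                        apex_rt = numeric(0), sigma = numeric(0),
                        in_blank = logical(0))),
      class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> seed %d: %d spiked precursor(s), %d background, %d fragment rows\n",
    x$seed, sum(!x$compounds$in_blank), sum(x$compounds$in_blank),
    nrow(x$fragments)))
  invisible(x)
}

#' Write / read a ground-truth object as JSON
#' @param truth a \code{\link{make_ground_truth}} object.
#' @param path JSON file.
#' @return path (writer, invisibly) or the truth object (reader).
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  obj$compounds <- as.data.frame(obj$compounds)
  obj$fragments <- as.data.frame(obj$fragments)
  structure(obj, class = "ground_truth")
}

.gauss_points <- function(times, apex, sigma, height, floor_counts = 0.5) {
  y <- height * exp(-(times - apex)^2 / (2 * sigma^2))
  keep <- y > floor_counts
  list(idx = which(keep), y = y[keep])
}

.shot_noise <- function(y, baseline_sd) {
  if (baseline_sd <= 0) return(y)
  pmax(0, y + stats::rnorm(length(y), 0, pmax(baseline_sd, sqrt(y))))
}

#' Simulate a SWATH (or IDA) sample/blank run pair
#'
#' SWATH mode emits full cycles (one MS1 survey scan plus one MS2 scan per
#' isolation window). IDA mode emits one MS1 scan per cycle followed by up
#' to 15 precursor-triggered MS2 scans for precursors above 200 counts,
#' with a 3-second dynamic-exclusion window after three successive
#' selections. The blank shares the acquisition geometry and the noise
#' model and carries the truth's background compounds but never the spiked
#' ones. Regenerating from the same truth is bit-identical.
#'
#' @param truth a \code{\link{make_ground_truth}} object.
#' @param scheme a \code{\link{swath_scheme}}; must cover the truth's
#'   precursors.
#' @param mode "swath" or "ida".
#' @return list(sample, blank) of \code{\link{ms_run}} objects.
#' @export
simulate_run <- function(truth, scheme = swath_scheme(),
                         mode = c("swath", "ida")) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "ground_truth"))
  if (nrow(truth$compounds) &&
      (min(truth$compounds$precursor_mz) < scheme$start ||
       max(truth$compounds$precursor_mz) > scheme$end))
    stop("truth precursors outside the window scheme's range")
  base <- truth$seed * 4L + if (mode == "ida") 1013L else 11L
  list(
    sample = .simulate_one(truth, scheme, mode, blank = FALSE, seed = base),
    blank = .simulate_one(truth, scheme, mode, blank = TRUE, seed = base + 1L))
}

.simulate_one <- function(truth, scheme, mode, blank, seed) {
  .with_seed(seed, {
    nw <- n_windows(scheme)
    cyc <- seq(truth$run_rt[1], truth$run_rt[2], by = truth$cycle_time)
    ncyc <- length(cyc)
    comp <- truth$compounds[truth$compounds$in_blank | !blank, , drop = FALSE]
    frag <- truth$fragments[truth$fragments$in_blank | !blank, , drop = FALSE]
    # injection-to-injection variability: each compound's whole elution
    # profile (precursor and fragments together) shifts and re-widens by a
    # common per-run factor, so parent-fragment co-elution is preserved but
    # separately acquired runs (e.g. an IDA/SWATH calibration pair) differ
    if (nrow(comp)) {
      keys <- unique(comp$splash_id)
      j_rt <- stats::setNames(stats::rnorm(length(keys), 1,
                                           truth$rt_jitter_sd), keys)
      j_w <- stats::setNames(stats::rnorm(length(keys), 1,
                                          truth$width_jitter_sd), keys)
      comp$apex_rt <- comp$apex_rt * j_rt[comp$splash_id]
      comp$sigma <- comp$sigma * j_w[comp$splash_id]
      if (nrow(frag)) {
        frag$apex_rt <- frag$apex_rt * j_rt[frag$splash_id]
        frag$sigma <- frag$sigma * j_w[frag$splash_id]
      }
    }
    ppm_sd <- truth$mass_error_ppm_sd
    bl_sd <- truth$noise$baseline_sd
    mz_jit <- function(mz, n)
      mz * (1 + stats::rnorm(n, 0, ppm_sd * 1e-6))
    if (mode == "swath") {
      per_cycle <- nw + 1L
      n <- ncyc * per_cycle
      lvl <- rep(c(1L, rep(2L, nw)), ncyc)
      widx <- rep(c(NA_integer_, seq_len(nw) - 1L), ncyc)
      rt <- rep(cyc, each = per_cycle) +
        rep(seq_len(per_cycle) - 1L, ncyc) * truth$cycle_time / per_cycle
      scans <- data.frame(
        ms_level = lvl, rt = rt,
        window_lo = ifelse(is.na(widx), NA_real_, scheme$windows[widx + 1L, "lo"]),
        window_hi = ifelse(is.na(widx), NA_real_, scheme$windows[widx + 1L, "hi"]))
      ms1_scans <- which(lvl == 1L)
      scan_of_window <- lapply(seq_len(nw) - 1L,
                               function(w) which(!is.na(widx) & widx == w))
    } else {
      # IDA: decide triggers cycle by cycle from the noiseless MS1 profile
      ms1_int <- if (nrow(comp)) {
        vapply(seq_len(nrow(comp)), function(i)
          comp$height[i] * exp(-(cyc - comp$apex_rt[i])^2 /
                                 (2 * comp$sigma[i]^2)), numeric(ncyc))
      } else matrix(numeric(0), nrow = ncyc, ncol = 0)
      if (!is.matrix(ms1_int)) ms1_int <- matrix(ms1_int, nrow = ncyc)
      streak <- integer(nrow(comp)); excl_until <- numeric(nrow(comp))
      sel_list <- vector("list", ncyc)
      for (c_i in seq_len(ncyc)) {
        ints <- if (nrow(comp)) ms1_int[c_i, ] else numeric(0)
        elig <- which(ints > 200 & cyc[c_i] >= excl_until)
        sel <- elig[order(-ints[elig])]
        sel <- sel[seq_len(min(15L, length(sel)))]
        streak[sel] <- streak[sel] + 1L
        streak[setdiff(seq_len(nrow(comp)), sel)] <- 0L
        hit3 <- which(streak >= 3L)
        excl_until[hit3] <- cyc[c_i] + 3 / 60   # 3 s dynamic exclusion
        streak[hit3] <- 0L
        sel_list[[c_i]] <- sel
      }
      per_cycle_n <- vapply(sel_list, length, integer(1)) + 1L
      n <- sum(per_cycle_n)
      lvl <- integer(n); rt <- numeric(n)
      wlo <- rep(NA_real_, n); whi <- rep(NA_real_, n)
      trig <- rep(NA_integer_, n)
      pos <- 1L
      for (c_i in seq_len(ncyc)) {
        k <- per_cycle_n[c_i]
        rows <- pos:(pos + k - 1L)
        lvl[rows] <- c(1L, rep(2L, k - 1L))
        rt[rows] <- cyc[c_i] + (seq_len(k) - 1L) * truth$cycle_time / k
        if (k > 1L) {
          mzs <- comp$precursor_mz[sel_list[[c_i]]]
          wlo[rows[-1]] <- mzs - 0.35
          whi[rows[-1]] <- mzs + 0.35
          trig[rows[-1]] <- sel_list[[c_i]]
        }
        pos <- pos + k
      }
      scans <- data.frame(ms_level = lvl, rt = rt,
                          window_lo = wlo, window_hi = whi)
      ms1_scans <- which(lvl == 1L)
    }
    pk_scan <- list(); pk_mz <- list(); pk_int <- list()
    add <- function(scan_idx, mz, int) {
      k <- length(pk_scan) + 1L
      pk_scan[[k]] <<- scan_idx; pk_mz[[k]] <<- mz; pk_int[[k]] <<- int
    }
    # precursor traces in MS1
    for (i in seq_len(nrow(comp))) {
      g <- .gauss_points(scans$rt[ms1_scans], comp$apex_rt[i], comp$sigma[i],
                         comp$height[i])
      if (!length(g$idx)) next
      y <- .shot_noise(g$y, bl_sd)
      add(ms1_scans[g$idx], mz_jit(comp$precursor_mz[i], length(g$idx)), y)
    }
    # fragment traces in the precursor's MS2 scans
    for (i in seq_len(nrow(frag))) {
      f_scans <- if (mode == "swath") {
        scan_of_window[[frag$window_index[i] + 1L]]
      } else {
        prec_rows <- which(comp$splash_id == frag$splash_id[i] &
                             comp$adduct == frag$adduct[i])
        which(!is.na(trig) & trig %in% prec_rows)
      }
      if (!length(f_scans)) next
      g <- .gauss_points(scans$rt[f_scans], frag$apex_rt[i], frag$sigma[i],
                         frag$height[i])
      if (!length(g$idx)) next
      y <- .shot_noise(g$y, bl_sd)
      add(f_scans[g$idx], mz_jit(frag$mz[i], length(g$idx)), y)
    }
    # random background centroids on every scan
    nn <- truth$noise$n_noise_peaks
    if (nn > 0) {
      n_tot <- n * nn
      add(rep(seq_len(n), each = nn),
          stats::runif(n_tot, scheme$start, scheme$end),
          abs(stats::rnorm(n_tot, truth$noise$noise_mean,
                           truth$noise$noise_mean / 2)))
    }
    sc_v <- unlist(pk_scan, use.names = FALSE)
    peaks <- data.frame(
      scan = if (is.null(sc_v)) integer(0) else sc_v,
      mz = if (is.null(sc_v)) numeric(0) else unlist(pk_mz, use.names = FALSE),
      intensity = if (is.null(sc_v)) numeric(0)
                  else unlist(pk_int, use.names = FALSE))
    if (nrow(peaks)) peaks <- peaks[peaks$intensity > 0, , drop = FALSE]
    ms_run(scans, peaks, scheme = scheme, polarity = truth$polarity)
  })
}
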