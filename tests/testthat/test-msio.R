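# mzML round-trip and XIC extraction.

study <- small_study(seed = 21, n_lib = 8, n_spike = 3, run_rt = c(0, 2.5))

test_that("mzML write/read round-trips scans, ordering and centroids", {
  run <- study$sample
  f <- withr::local_tempfile(fileext = ".mzML")
  write_ms_run(run, f)
  back <- read_ms_run(f)
  expect_equal(nrow(back$scans), nrow(run$scans))
  expect_identical(back$scans$ms_level, as.integer(run$scans$ms_level))
  expect_equal(back$scans$rt, run$scans$rt, tolerance = 1e-9)
  expect_equal(length(back$pk_mz), length(run$pk_mz))
  expect_lt(max(abs(back$pk_mz - run$pk_mz)), 1e-6)
  expect_equal(back$pk_int, run$pk_int, tolerance = 1e-6)
  expect_identical(back$scans$window_index, run$scans$window_index)
})

test_that("a synthetic SWATH run exposes all 21 isolation windows", {
  f <- withr::local_tempfile(fileext = ".mzML")
  write_ms_run(study$sample, f)
  back <- read_ms_run(f)
  expect_equal(length(unique(na.omit(back$scans$window_index))), 21)
  expect_equal(nrow(back$scheme$windows), 21)
})

test_that("MS1-only and empty runs are handled", {
  ms1 <- ms_run(data.frame(ms_level = rep(1L, 6), rt = (0:5) / 100),
                data.frame(scan = 1:6, mz = rep(100.05, 6),
                           intensity = rep(10, 6)))
  expect_null(ms1$scheme)
  f <- withr::local_tempfile(fileext = ".mzML")
  write_ms_run(ms1, f)
  back <- read_ms_run(f)
  expect_equal(sum(back$scans$ms_level == 2L), 0)
  expect_null(back$scheme)
  empty <- ms_run(data.frame(ms_level = integer(0), rt = numeric(0)),
                  data.frame(scan = integer(0), mz = numeric(0),
                             intensity = numeric(0)))
  f2 <- withr::local_tempfile(fileext = ".mzML")
  write_ms_run(empty, f2)
  expect_equal(nrow(read_ms_run(f2)$scans), 0)
})

test_that("truncated files and profile-mode data are rejected", {
  f <- withr::local_tempfile(fileext = ".mzML")
  write_ms_run(study$sample, f)
  txt <- readBin(f, "raw", file.size(f))
  f_trunc <- withr::local_tempfile(fileext = ".mzML")
  writeBin(txt[seq_len(length(txt) %/% 3)], f_trunc)
  expect_error(read_ms_run(f_trunc), "format error")

  f_prof <- withr::local_tempfile(fileext = ".mzML")
  hdr <- data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
    peaksCount = 2L, totIonCurrent = 3, retentionTime = 1,
    basePeakMZ = 100, basePeakIntensity = 2, collisionEnergy = 0,
    ionisationEnergy = 0, lowMZ = 100, highMZ = 200, precursorScanNum = 0L,
    precursorMZ = 0, precursorCharge = 0L, precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 0,
    filterString = NA_character_, spectrumId = "scan=1", centroided = FALSE,
    ionMobilityDriftTime = NA_real_, isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_, isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = 50, scanWindowUpperLimit = 1100)
  mzR::writeMSData(list(cbind(mz = c(100, 200), intensity = c(1, 2))),
                   file = f_prof, header = hdr)
  expect_error(read_ms_run(f_prof), "profile")
})

test_that("MS2 scans must carry isolation windows; RTs must be ordered", {
  expect_error(
    ms_run(data.frame(ms_level = c(1L, 2L), rt = c(0, 0.01)),
           data.frame(scan = 1L, mz = 100, intensity = 1)),
    "isolation-window")
  expect_error(
    ms_run(data.frame(ms_level = c(1L, 1L), rt = c(1, 0.5)),
           data.frame(scan = 1L, mz = 100, intensity = 1)),
    "non-decreasing")
})

test_that("XIC extraction covers every qualifying scan and only those", {
  run <- study$sample
  prec <- study$gt$compounds[1, ]
  x1 <- extract_xic(run, 1L, prec$precursor_mz, 0.01)
  expect_equal(nrow(x1), sum(run$scans$ms_level == 1L))
  expect_gt(max(x1$intensity), 0.5 * prec$height)
  # absent target: all zeros
  x0 <- extract_xic(run, 1L, 1099.95, 0.003)
  expect_equal(nrow(x0), sum(run$scans$ms_level == 1L))
  expect_true(all(x0$intensity >= 0))
  # MS2 extraction never mixes isolation windows
  frag <- study$gt$fragments[1, ]
  x2 <- extract_xic(run, 2L, frag$mz, 0.05, frag$window_index)
  expect_true(all(run$scans$window_index[attr(x2, "scan")] ==
                    frag$window_index))
  expect_error(extract_xic(run, 2L, frag$mz, 0.05, 99L), "window_index")
  expect_error(extract_xic(run, 2L, frag$mz, 0.05), "required")
})

test_that("fragment XIC reproduces the simulated profile within 2%", {
  quiet <- small_study(seed = 5, n_lib = 6, n_spike = 2, run_rt = c(0, 2.5),
                       baseline_sd = 0.5, n_noise_peaks = 0,
                       rt_jitter_sd = 0, width_jitter_sd = 0,
                       mass_error_ppm_sd = 0)
  frag <- quiet$gt$fragments
  frag <- frag[which.max(frag$height), ]
  x <- extract_xic(quiet$sample, 2L, frag$mz, 0.05, frag$window_index)
  expect_equal(max(x$intensity), frag$height, tolerance = 0.02)
  pk <- detect_peak(x)
  expect_equal(pk$height, frag$height, tolerance = 0.02)
  expect_equal(pk$apex_rt, frag$apex_rt, tolerance = 0.005)
})

test_that("XIC extraction is additive over a partition of the window", {
  run <- study$sample
  mz0 <- study$gt$compounds$precursor_mz[2]
  whole <- extract_xic(run, 1L, mz0, 0.04)
  # partition [mz0-0.04, mz0+0.04] into four adjacent slices
  edges <- seq(mz0 - 0.04, mz0 + 0.04, length.out = 5)
  parts <- lapply(seq_len(4), function(i) {
    c <- (edges[i] + edges[i + 1]) / 2
    extract_xic(run, 1L, c, (edges[i + 1] - edges[i]) / 2)
  })
  summed <- Reduce(`+`, lapply(parts, `[[`, "intensity"))
  # boundary centroids could be double-counted only if they sat exactly on
  # an edge; with continuous simulated m/z values the sums agree
  expect_equal(summed, whole$intensity, tolerance = 1e-12)
})
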