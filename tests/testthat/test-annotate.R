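# Fragment alignment, filtration, scoring and redundancy resolution.

study <- small_study(seed = 29, n_lib = 20, n_spike = 8)

test_that("shift equations are plain relative differences", {
  expect_equal(rt_shift(10, 10), 0)
  expect_equal(rt_shift(10, 10.001), 1e-4)
  expect_gt(rt_shift(10, 10.02), 0.001417)   # fails the default gate
  expect_error(rt_shift(0, 1), "parent RT")
  expect_equal(width_shift(0.10, 0.10), 0)
  expect_equal(width_shift(0.10, 0.12), 0.2)
  expect_lt(width_shift(0.10, 0.115), 0.174965)
  expect_error(width_shift(0, 0.1), "parent FWHM")
  # scale invariance
  for (c_scale in c(0.1, 7)) {
    expect_equal(rt_shift(3 * c_scale, 3.001 * c_scale), rt_shift(3, 3.001))
    expect_equal(width_shift(0.1 * c_scale, 0.13 * c_scale),
                 width_shift(0.1, 0.13))
  }
})

test_that("co-eluting fragments align within the default gates", {
  cands <- screen_precursors(study$sample, study$blank, study$lib$entries)
  cand <- cands[cands$compound_id == study$spiked[1], ][1, ]
  entry <- Filter(function(e) e$compound_id == cand$compound_id,
                  study$lib$entries)[[1]]
  al <- align_fragments(cand, study$sample, entry,
                        blank = study$blank)
  expect_equal(nrow(al), nrow(entry$fragments))
  found <- al[al$found, ]
  expect_gt(nrow(found), 0)
  expect_true(all(found$rt_shift < 0.001417))
  expect_true(all(found$width_shift < 0.174965))
})

test_that("a fragment displaced by 0.5 min is aligned but not retained", {
  gt_off <- study$gt
  spl <- gt_off$compounds$splash_id[1]
  i <- which(gt_off$fragments$splash_id == spl)[1]
  gt_off$fragments$apex_rt[i] <- gt_off$fragments$apex_rt[i] + 0.5
  runs <- simulate_run(gt_off)
  cands <- screen_precursors(runs$sample, runs$blank, study$lib$entries)
  cand <- cands[cands$splash_id == spl, ][1, ]
  entry <- Filter(function(e) e$splash_id == spl, study$lib$entries)[[1]]
  al <- apply_filtration(align_fragments(cand, runs$sample, entry,
                                         blank = runs$blank))
  j <- which.min(abs(al$library_mz - gt_off$fragments$mz[i]))
  expect_false(al$retained[j])
})

test_that("filtration recomputes relative intensities in two passes", {
  frags <- data.frame(
    library_mz = c(100, 150, 200), tag = c("D", "F", "F"),
    library_relative_intensity = c(100, 40, 6), found = TRUE,
    apex_rt = 2, height = c(1000, 400, 30), fwhm = 0.1, snr = 100,
    rt_shift = 1e-5, width_shift = 0.01, blank_ratio = Inf,
    observed_relative_intensity = NA_real_, retained = FALSE,
    window_index = 3L)
  out <- apply_filtration(frags)
  expect_equal(out$observed_relative_intensity, c(100, 40, 3))
  expect_equal(out$retained, c(TRUE, TRUE, FALSE))
  # all failing the shift gates leaves nothing retained
  frags$rt_shift <- 0.01
  expect_false(any(apply_filtration(frags)$retained))
  # a single passing fragment becomes the base peak
  one <- frags[1, ]; one$rt_shift <- 0
  out1 <- apply_filtration(one)
  expect_equal(out1$observed_relative_intensity, 100)
  expect_true(out1$retained)
})

test_that("the score reaches 1 for perfect recovery and follows the formula", {
  frags <- data.frame(
    library_mz = c(100, 150), tag = c("D", "F"),
    library_relative_intensity = c(100, 50), found = TRUE, apex_rt = 2,
    height = c(1000, 500), fwhm = 0.1, snr = 100, rt_shift = 0,
    width_shift = 0, blank_ratio = Inf,
    observed_relative_intensity = c(100, 50), retained = TRUE,
    window_index = 3L)
  expect_equal(score_identification(frags), 1.0)
  # only the main daughter recovered, zero shift, exact intensity:
  # 0.5 * w_D / W + 0.3 + 0.2
  only_d <- frags; only_d$retained <- c(TRUE, FALSE)
  expect_equal(score_identification(only_d),
               0.5 * (100 / 150) + 0.3 + 0.2)
  none <- frags; none$retained <- FALSE
  expect_true(is.na(score_identification(none)))
})

make_id <- function(compound, ppm, frag_mz, frag_rt, window = 3L,
                    score = 0.9, tag = "D") {
  n <- length(frag_mz)
  structure(list(
    compound_id = compound, splash_id = paste0("spl-", compound),
    compound_name = compound, adducts = "[M+H]+",
    candidate = list(adduct = "[M+H]+", ppm_error = ppm, library_mz = 200,
                     observed_mz = 200, window_index = window, apex_rt = 2,
                     height = 1e4, fwhm = 0.1, snr = 1000,
                     blank_ratio = Inf),
    fragments = data.frame(
      library_mz = frag_mz, tag = rep_len(tag, n),
      library_relative_intensity = rep(100, n), found = TRUE,
      apex_rt = frag_rt, height = 1000, fwhm = 0.1, snr = 100,
      rt_shift = 0, width_shift = 0, blank_ratio = Inf,
      observed_relative_intensity = 100, retained = TRUE,
      window_index = window),
    has_D = TRUE, score = score), class = "identification")
}

test_that("a shared fragment XIC goes to the lower-ppm identification", {
  a <- make_id("A", ppm = 1, frag_mz = c(120.05, 180.09),
               frag_rt = c(2.0, 2.0))
  b <- make_id("B", ppm = 6, frag_mz = c(120.053, 250.1),
               frag_rt = c(2.0001, 2.0))
  out <- dedup_redundant(list(a, b))
  byid <- setNames(out, vapply(out, `[[`, character(1), "compound_id"))
  expect_true(byid$A$fragments$retained[1])
  expect_false(byid$B$fragments$retained[1])
  expect_true(byid$B$fragments$retained[2])  # unshared fragment survives
})

test_that("disjoint identifications pass dedup unchanged", {
  a <- make_id("A", 1, c(120.05), 2.0)
  b <- make_id("B", 6, c(320.07), 2.0)
  out <- dedup_redundant(list(a, b))
  expect_length(out, 2)
  expect_true(all(vapply(out, function(x) all(x$fragments$retained),
                         logical(1))))
})

test_that("multiple adducts of one compound merge into one identification", {
  gt2 <- make_ground_truth(study$lib$entries, n_spike = 3, seed = 67,
                           adducts = c("[M+H]+", "[M+Na]+"),
                           run_rt = c(0, 4.5))
  runs <- simulate_run(gt2)
  ids <- annotate_run(runs$sample, runs$blank, study$lib$entries)
  tab <- identifications_table(ids)
  expect_false(any(duplicated(tab$compound_id)))
  spiked2 <- unique(gt2$compounds$compound_id)
  both <- tab$adducts[tab$compound_id %in% spiked2]
  expect_true(any(grepl(";", both)))
})

test_that("end-to-end annotation recovers the spiked compounds exactly", {
  ids <- annotate_run(study$sample, study$blank, study$lib$entries)
  tab <- identifications_table(ids)
  expect_setequal(tab$compound_id, study$spiked)
  # every reported identification carries a retained main daughter
  for (id in ids)
    expect_true(any(id$fragments$tag == "D" & id$fragments$retained))
})

test_that("self-blank and empty-library runs yield no identifications", {
  ids_self <- annotate_run(study$sample, study$sample, study$lib$entries)
  expect_length(ids_self, 0)
  ids_empty <- annotate_run(study$sample, study$blank, list())
  expect_length(ids_empty, 0)
})

test_that("tightening thresholds never adds identifications or fragments", {
  default <- filtration_params()
  tight <- filtration_params(rt_shift_max = 0.001417 / 3,
                             width_shift_max = 0.174965 / 3,
                             rel_int_min_pct = 15, snr_min = 100,
                             screen_blank_ratio_min = 10,
                             filter_blank_ratio_min = 10)
  ids_d <- annotate_run(study$sample, study$blank, study$lib$entries, default)
  ids_t <- annotate_run(study$sample, study$blank, study$lib$entries, tight)
  tab_d <- identifications_table(ids_d); tab_t <- identifications_table(ids_t)
  expect_true(all(tab_t$compound_id %in% tab_d$compound_id))
  ft_d <- fragments_table(ids_d); ft_t <- fragments_table(ids_t)
  kd <- paste(ft_d$compound_id, ft_d$library_mz)[ft_d$retained]
  kt <- paste(ft_t$compound_id, ft_t$library_mz)[ft_t$retained]
  expect_true(all(kt %in% kd))
})

test_that("annotation is deterministic given identical inputs", {
  t1 <- identifications_table(
    annotate_run(study$sample, study$blank, study$lib$entries))
  t2 <- identifications_table(
    annotate_run(study$sample, study$blank, study$lib$entries))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write.csv(t1, f1, row.names = FALSE); write.csv(t2, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})
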