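# Spectral-library parsing and curation into the DIA transition database.

test_that("MSP parsing preserves record count, fields and SPLASH ids", {
  sp <- parse_spectra(msp_fixture_lines(), "msp")
  expect_length(sp, 2)
  expect_identical(sp[[1]]$splash_id, "splash10-trp-test")
  expect_identical(sp[[2]]$splash_id, "splash10-second")
  expect_equal(sp[[1]]$neutral_mass, 204.089878)
  expect_identical(sp[[1]]$polarity, "positive")
  expect_equal(nrow(sp[[1]]$fragments), 3)
  expect_equal(sp[[1]]$collision_energy, 35)
})

test_that("malformed records raise errors naming the record", {
  bad <- c("NAME: broken", "SPLASH: s1", "EXACTMASS: 100.0",
           "IONMODE: Positive", "Num Peaks: 1", "50.0 -10", "")
  expect_error(parse_spectra(bad, "msp"), "record 1.*>= 0")
  expect_error(parse_spectra(bad, "nonsense"), "arg")
})

test_that("zero-fragment records are reported and dropped", {
  lines <- c(msp_fixture_lines(),
             "NAME: fragmentless", "SPLASH: s3", "EXACTMASS: 120.0",
             "IONMODE: Positive", "Num Peaks: 0", "")
  expect_warning(sp <- parse_spectra(lines, "msp"), "zero fragments")
  expect_length(sp, 2)
})

test_that("csv and json dialects reproduce the msp content exactly", {
  sp <- parse_spectra(msp_fixture_lines(), "msp")
  for (dialect in c("csv", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_spectra(sp, f, dialect)
    sp2 <- parse_spectra(f, dialect)
    expect_length(sp2, length(sp))
    for (i in seq_along(sp)) {
      expect_identical(sp2[[i]]$splash_id, sp[[i]]$splash_id)
      expect_equal(sp2[[i]]$neutral_mass, sp[[i]]$neutral_mass,
                   tolerance = 1e-6)
      expect_equal(sp2[[i]]$fragments$mz, sp[[i]]$fragments$mz,
                   tolerance = 1e-6)
      expect_equal(sp2[[i]]$fragments$intensity, sp[[i]]$fragments$intensity,
                   tolerance = 1e-6)
    }
  }
})

test_that("normalize_relative scales the base peak to exactly 100", {
  n <- normalize_relative(data.frame(mz = 1:3, intensity = c(200, 100, 10)))
  expect_equal(n$relative_intensity, c(100, 50, 5))
  expect_equal(normalize_relative(
    data.frame(mz = 1:2, intensity = c(7, 7)))$relative_intensity, c(100, 100))
  expect_equal(normalize_relative(
    data.frame(mz = 1, intensity = 42))$relative_intensity, 100)
  expect_error(normalize_relative(data.frame(mz = 1:2, intensity = c(0, 0))),
               "degenerate")
})

test_that("tag_and_filter applies the strict 5/75 boundary semantics", {
  tf <- function(rel) tag_and_filter(
    data.frame(mz = seq_along(rel), relative_intensity = rel))
  r <- tf(c(100, 60, 3))
  expect_equal(r$relative_intensity, c(100, 60))
  expect_equal(r$tag, c("D", "F"))
  expect_equal(tf(c(100, 80))$tag, c("D", "D"))      # several main daughters
  r <- tf(c(100, 75, 5))                             # boundaries are strict
  expect_equal(r$tag, c("D", "F", "F"))
  expect_equal(nrow(tf(c(4, 3))), 0)
})

test_that("collapse_near_duplicates merges repeated transitions", {
  # 19 distinct m/z (1 Da apart) plus 9 near-duplicates within tolerance,
  # mirroring a 28-transition list in which 9 recur with a slight mass shift
  base <- data.frame(mz = 100 + seq_len(19),
                     relative_intensity = seq(100, 10, length.out = 19))
  dup <- data.frame(mz = base$mz[1:9] + 0.004,
                    relative_intensity = base$relative_intensity[1:9] - 1)
  all28 <- rbind(base, dup)
  out <- collapse_near_duplicates(all28, mz_tol = 0.01)
  expect_equal(nrow(out), 19)
  expect_true(all(out$relative_intensity %in% base$relative_intensity))
  # widely spaced input is untouched
  expect_equal(collapse_near_duplicates(base, 0.01), base)
  # exact duplicate keeps the higher intensity
  two <- data.frame(mz = c(50, 50), relative_intensity = c(40, 90))
  expect_equal(collapse_near_duplicates(two, 0.01)$relative_intensity, 90)
})

test_that("build_dia_entry attaches one precursor per in-range adduct", {
  e <- build_dia_entry(trp_spectrum())
  expect_s3_class(e, "dia_entry")
  expect_equal(nrow(e$precursors), 5)  # all five positive-mode adducts
  expect_equal(sort(e$precursors$adduct),
               sort(adduct_table("positive")$name))
  mh <- e$precursors[e$precursors$adduct == "[M+H]+", ]
  expect_equal(mh$mz, 205.09715, tolerance = 1e-5)
  expect_equal(mh$window_index, 3L)
  expect_true(any(e$fragments$tag == "D"))
  expect_true(all(diff(e$fragments$relative_intensity) <= 0))
})

test_that("spectra without a main daughter or out of range are rejected", {
  # the base peak (the only D here) sits below the 50 Da acquisition floor,
  # so range filtering strips the main daughter and the spectrum is rejected
  low_d <- library_spectrum("s1", "c1", "lowD", 204.09, "positive",
                            data.frame(mz = c(45.03, 120.05),
                                       intensity = c(1000, 300)))
  r <- build_dia_entry(low_d)
  expect_s3_class(r, "dia_rejection")
  expect_match(r$reason, "no main daughter")
  # a 2000 Da neutral puts every adduct above the 1100 Da ceiling
  heavy <- library_spectrum("s2", "c2", "heavy", 2000, "positive",
                            data.frame(mz = 500, intensity = 100))
  r2 <- build_dia_entry(heavy)
  expect_s3_class(r2, "dia_rejection")
  expect_match(r2$reason, "outside acquisition range")
  ok <- library_spectrum("s3", "c3", "fine", 204.09, "positive",
                         data.frame(mz = c(100, 120),
                                    intensity = c(100, 74)))
  expect_s3_class(build_dia_entry(ok), "dia_entry")
})

test_that("curation is idempotent and never increases fragment counts", {
  set.seed(31)
  for (rep in 1:10) {
    nf <- sample(3:12, 1)
    frag <- data.frame(mz = sort(runif(nf, 60, 400)),
                       intensity = runif(nf, 1, 1000))
    once <- collapse_near_duplicates(
      tag_and_filter(normalize_relative(frag)), 0.01)
    twice <- collapse_near_duplicates(
      tag_and_filter(once[, c("mz", "relative_intensity")]), 0.01)
    expect_equal(twice$relative_intensity, once$relative_intensity)
    expect_equal(twice$mz, once$mz)
    expect_lte(nrow(once), nf)
    if (nrow(once)) expect_true(all(once$relative_intensity >= 5))
  }
})

test_that("every curated library entry keeps at least one D fragment", {
  lib <- make_synthetic_library(40, seed = 3)
  expect_true(all(vapply(lib$entries,
                         function(e) any(e$fragments$tag == "D"),
                         logical(1))))
})

test_that("the DIA database round-trips through CSV and JSON", {
  lib <- make_synthetic_library(6, seed = 9)
  for (fmt in c("csv", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_dia_library(lib$entries, f)
    back <- read_dia_library(f)
    expect_length(back, length(lib$entries))
    for (i in seq_along(back)) {
      expect_identical(back[[i]]$splash_id, lib$entries[[i]]$splash_id)
      expect_equal(back[[i]]$precursors$mz, lib$entries[[i]]$precursors$mz,
                   tolerance = 1e-9)
      expect_equal(back[[i]]$fragments$relative_intensity,
                   lib$entries[[i]]$fragments$relative_intensity,
                   tolerance = 1e-9)
      expect_identical(back[[i]]$fragments$tag, lib$entries[[i]]$fragments$tag)
    }
  }
})
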