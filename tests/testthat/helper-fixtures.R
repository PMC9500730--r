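# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write.

gauss <- function(t, h, mu, sigma) h * exp(-(t - mu)^2 / (2 * sigma^2))

# bare XIC object for peak-measurement tests
xic_obj <- function(rt, intensity) {
  structure(data.frame(rt = rt, intensity = intensity),
            target_mz = NA_real_, tol = NA_real_, ms_level = 1L,
            window_index = NA_integer_, scan = seq_along(rt),
            class = c("xic", "data.frame"))
}

# a tryptophan-like spectrum: neutral mass of C11H12N2O2 with a plausible
# fragment ladder spanning the D / F / excluded intensity bands
trp_spectrum <- function() {
  library_spectrum(
    splash_id = "splash10-trp-test", compound_id = "HMDB0000929",
    compound_name = "tryptophan-like standard", neutral_mass = 204.08988,
    polarity = "positive",
    fragments = data.frame(
      mz = c(188.0706, 146.0600, 118.0651, 144.0808, 159.0917, 91.0542),
      intensity = c(1000, 820, 460, 220, 90, 30)))
}

msp_fixture_lines <- function() {
  c("NAME: tryptophan-like standard",
    "COMPOUND_ID: HMDB0000929",
    "SPLASH: splash10-trp-test",
    "EXACTMASS: 204.089878",
    "IONMODE: Positive",
    "RESOLUTION: high",
    "COLLISIONENERGY: 35",
    "Num Peaks: 3",
    "188.0706 1000",
    "146.0600 820",
    "118.0651 460",
    "",
    "NAME: second compound",
    "COMPOUND_ID: CMP002",
    "SPLASH: splash10-second",
    "EXACTMASS: 180.063388",
    "IONMODE: Positive",
    "Num Peaks: 2",
    "163.0601 500",
    "135.0441 250",
    "")
}

# small synthetic study used by several test files (cheap to rebuild)
small_study <- function(seed = 11, n_lib = 15, n_spike = 5,
                        run_rt = c(0, 4.5), ...) {
  lib <- make_synthetic_library(n_lib, seed = seed)
  gt <- make_ground_truth(lib$entries, n_spike = n_spike, seed = seed,
                          run_rt = run_rt, ...)
  runs <- simulate_run(gt)
  list(lib = lib, gt = gt, sample = runs$sample, blank = runs$blank,
       spiked = unique(gt$compounds$compound_id[!gt$compounds$in_blank]))
}
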