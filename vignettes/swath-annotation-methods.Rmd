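---
title: "Methods: library-guided annotation of SWATH metabolomics runs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: library-guided annotation of SWATH metabolomics runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The annotation model

SWATH acquisition records, every cycle, one MS1 survey scan over the
acquisition range (50–1100 Da by default) and one MS2 scan per fixed
isolation window (21 windows of 50 Da). All precursors in a window are
co-fragmented, so an MS2 spectrum is a mixture and fragment–precursor links
must be reconstructed. swathAnnotator does this with a priori knowledge from
an MS/MS spectral library and two chromatographic co-elution statistics:

$$\mathrm{rt\_shift} = \frac{|RT_{parent} - RT_{fragment}|}{RT_{parent}},
\qquad
\mathrm{width\_shift} = \frac{|FWHM_{parent} - FWHM_{fragment}|}{FWHM_{parent}}$$

Both are dimensionless fractions, invariant under rescaling of the time
axis. A library fragment is accepted as evidence for a candidate precursor
only if its XIC, extracted in the precursor's own isolation window, forms a
peak near the precursor's apex with both shifts below their thresholds.

The pipeline assumes centroided data, singly charged species, and
approximately Gaussian elution peaks; it performs no deconvolution — a
fragment XIC contaminated by a co-eluting isobar in the same window is
handled by the blank-ratio and de-duplication gates, not by peak-shape
modelling.

# Tunable parameters

All gates live in one object, `filtration_params()`:

| parameter | default | unit | role |
|---|---|---|---|
| `ppm_tol` | 10 | ppm | MS1 precursor extraction half-window |
| `snr_min` | 30 | — | precursor XIC S/N gate (strict >) |
| `screen_blank_ratio_min` | 5 | — | sample:blank gate at screening (strict >) |
| `filter_blank_ratio_min` | 5 | — | blank gate at fragment filtration (inclusive ≥) |
| `frag_tol_da` | 0.05 | Da | MS2 fragment extraction half-window |
| `rt_shift_max` | 0.001417 | fraction | RT co-elution gate (< 0.1417%) |
| `width_shift_max` | 0.174965 | fraction | FWHM co-elution gate |
| `rel_int_min_pct` | 5 | % | relative-intensity floor (library and observed) |
| `d_threshold_pct` | 75 | % | main-daughter (D) tag threshold |
| `dedup_mz_tol` | 0.01 | Da | near-duplicate fragment collapse |

The screening blank gate is strict (`> 5`) while the filtration gate is
inclusive (`≥ 5`); the two stages are specified with different boundary
conventions and both are kept configurable rather than silently unified.

Two deliberately surfaced ambiguities:

* **The width-shift threshold's unit.** The operating point `17.4965` is
  quoted without a unit, while the equation it gates produces a fraction.
  The default reads it as a percentage (fraction 0.174965), which is the
  only reading on the same footing as the RT criterion ("0.1417%"). A
  literal mode (`width_shift_literal = TRUE`) applies the raw number as a
  fraction, which effectively disables the gate; choosing it is logged by
  the pipeline report.
* **The chloride adduct.** "[M−Cl]−" is chemically anomalous for most
  metabolites; the default negative-mode table implements chloride
  attachment [M+Cl]− (+34.9694013 Da), and `adduct_table(chloride =
  "literal")` provides the literal subtraction instead.

Adduct mass deltas are assembled from monoisotopic atomic masses with full
electron-mass accounting (one electron per unit of charge, ±0.000549 Da).
The proton delta is therefore +1.0072765 Da, not the hydrogen atom mass;
at 0.05 Da fragment windows the electron term is immaterial, but it keeps
every delta exact against an atomic-mass oracle, and the unit tests pin all
twelve species to that oracle.

SWATH window indices are 0-based throughout (`[50, 100) → 0`, …,
`[1050, 1100] → 20`): the index is an acquisition label shared with the
mzML isolation-window metadata, not an R vector subscript. Boundary m/z
values belong to the upper window (half-open convention); the top edge of
the last window is closed so the range maximum is assignable.

# Peak measurement

`detect_peak` smooths an XIC with a 5-point moving median followed by a
5-point moving mean — robust to single-scan spikes — but only to *locate*
the apex and to decide whether anything exceeds the noise floor
(median + 3 robust SD of the trace). Measurements come from the raw trace:

* **Apex RT and height** are the vertex of a least-squares parabola fitted
  to the log-intensities of the contiguous points ≥ 30% of the apex
  sample. A Gaussian is exactly quadratic in log-intensity, so the fit is
  unbiased for Gaussian peaks, averages down point noise, and localises the
  apex well below one sampling interval — necessary because the default
  RT-shift gate (0.1417% ≈ 0.85 s at 10 min) is tighter than one SWATH
  cycle. With fewer than four usable points the raw apex sample and a
  3-point parabola (vertex confined to ±half a sampling interval) are used;
  fitted heights outside [0.5, 2]× the raw apex sample fall back to the raw
  sample.
* **FWHM** is interpolated from the raw trace's half-height crossings,
  walking outward from the apex. Crossings are *not* taken on the smoothed
  trace: a 5-point moving mean at 0.01-min sampling would widen a
  σ = 0.02 min peak by over 20%. An edge peak missing one crossing reports
  twice the available half-width and is flagged.
* **S/N** is height over 1.4826 × the median absolute deviation of the
  intensities outside apex ± 2 FWHM, floored at one count. The vendor
  software whose S/N the 30-count threshold was defined against is a black
  box; the MAD estimator is a standard robust choice and the threshold
  stays configurable for that reason.
* A peak must span at least three consecutive nonzero scans; an isolated
  single-scan spike is never a peak. This single rule keeps the false
  candidate rate on noise-only runs below 1% without touching any
  threshold.

Peak-parameter recovery is verified on a grid of Gaussian peaks
(height 10²–10⁶, σ 0.02–0.2 min, additive noise 0–5% of height, 0.01-min
sampling) as the accuracy of the procedure: the mean of six replicate
traces per condition must recover height within 5% and FWHM within 10%,
and every individual trace must localise the apex within one sampling
interval. At the narrowest-peak/highest-noise corner a single trace carries
≈ 2.7% irreducible height uncertainty (the information limit of ~4
effective samples at 5% noise), so single-trace bounds there would measure
seed luck, not estimator quality.

# Filtration, scoring, redundancy

Filtration is two-pass: co-elution and blank gates first, then relative
intensities are recomputed with the *gate-passing* fragments' tallest XIC
as 100%. Using only shift-passing fragments as the base-peak reference
prevents a background-dominated tall XIC from compressing the scale and
dropping genuine fragments below the 5% floor.

An identification is emitted only if at least one retained fragment is a
main daughter (tag D) — precursors without a prominent daughter are
discarded. The score is

$$s = 0.5\,\frac{\sum_{retained} L_i}{\sum_{library} L_i}
    + 0.3\left(1 - \overline{\mathrm{rt\_shift}/\mathrm{rt\_shift\_max}}\right)
    + 0.2\,\cos(O, L)$$

with $L$ the library relative intensities and $O$ the observed ones over
retained fragments. The weights are configurable; the functional form is
this package's own design (the combination of fragment coverage, RT
agreement and spectral similarity is the information actually available
after filtration), reaching 1 exactly when every library fragment is
recovered at zero shift with library-identical relative intensities.

Redundancy is resolved in two steps: adducts of the same compound merge
into one identification (evidence from the lowest-|ppm| adduct, all adduct
names listed — cross-adduct redundancy is corroborating, not erroneous);
then a fragment XIC claimed by different compounds (same window, Δm/z ≤
0.01 Da, apex RTs within `rt_shift_max` of each other in relative terms)
is kept only for the identification with the smaller precursor |ppm error|,
ties broken by score. Identifications left without a retained D fragment
are dropped and scores recomputed.

# Threshold calibration

`estimate_thresholds` turns paired IDA/SWATH acquisitions of standards into
operating thresholds: per precursor matched in both runs it takes the
relative RT and FWHM shifts (`shift_observations`) and returns *k* × the
population standard deviation of each pooled shift set (default k = 1).
The statistic is deliberately pluggable — a pooled SD is the plainest
reading of "use the shift variability of standards as the criterion", but
nothing in the published operating point (0.1417% / 17.4965) is derivable
from it, so the calibrator reproduces the mechanism, not those constants.

# What the simulator emulates — and what it does not

`simulate_run` reproduces the acquisition geometry: cycles of one MS1 scan
plus 21 MS2 window scans (SWATH) or up to 15 intensity-triggered narrow-
window MS2 scans with a 200-count trigger floor and 3-s dynamic exclusion
(IDA). Study conditions, chosen once: 5-min runs at 0.01-min cycles, apex
RTs uniform in 1–4 min, Gaussian elution with σ = 0.05 min, spiked
precursor heights log-uniform in 10⁴–10⁵ counts, fragment heights
proportional to library relative intensities with 5% lognormal response
jitter, multiplicative RT jitter (SD 0.0005 × RT) and width jitter (SD 5%)
per fragment, a per-injection per-compound jitter of the same magnitudes
shared by a compound's precursor and fragments (so separately simulated
runs differ realistically while co-elution is preserved), 2-ppm m/z scan
error, shot noise with σ = max(baseline, √intensity), and ~15 random
background centroids per scan. Blanks share geometry and noise and carry
only the designated background compounds.

Not emulated: isotope envelopes, chimeric/shared fragments between
co-eluting compounds, baseline drift, RT gradients, detector saturation,
profile peak shapes, multiply charged species. Passing the synthetic suite
therefore demonstrates the pipeline's logic — gates, alignment, bookkeeping
— under controlled truth; it does not certify performance on matrix-heavy
biological runs, where interference and non-Gaussian peaks dominate the
error budget.

Test problem sizes are the package's own choice: the end-to-end suite uses
20 independent studies of a 50-compound library with 10 spiked compounds
each; the property suites use 12-compound libraries over 20 seeds. All
synthetic stages are seeded and regenerate bit-identically from a stored
ground-truth object.

# Degenerate inputs and tie-breaks

* XICs with fewer than 5 points raise an error; all-zero XICs return no
  peak.
* Ties in relative intensity at normalisation all become base peaks (100).
* Exactly 5% relative intensity is retained (tagged F); exactly 75% is F —
  both thresholds are strict as stated wherever they gate.
* Near-duplicate collapse is single-linkage on the sorted m/z ladder,
  keeping the most intense member of each cluster.
* With an RT prior, the local maximum nearest the expected RT wins; ties go
  to the taller. Without a prior, the tallest smoothed maximum wins.
* A missing blank run disables the blank gates (ratio +∞) with a warning.
* Greedy fragment-overlap matching sorts candidate pairs by |Δm/z| with
  ties toward lower m/z; each member matches at most once.

# Known limitations

* The curation treats SPLASH identifiers as opaque keys; no spectral
  hashing is computed or verified.
* Low-resolution library records are parsed and flagged but the pipeline's
  tolerances assume high-resolution data.
* The IDA emulation is the minimum needed to exercise calibration and
  overlap reporting, not a faithful DDA scheduler.
* `dedup_redundant` compares identifications pairwise; for libraries with
  thousands of simultaneous candidates in one window an indexed variant
  would be preferable.
* Quantification, batch alignment and isotope correction are out of scope.
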