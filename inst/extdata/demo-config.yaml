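# Demo pipeline configuration: simulate a 20-compound library with 6 spiked
# compounds and annotate the resulting SWATH run against it.
seed: 7
library:
  synthetic:
    n_compounds: 20
simulate:
  n_spike: 6
params:
  ppm_tol: 10
  snr_min: 30
  rt_shift_max: 0.001417
  width_shift_max: 0.174965
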