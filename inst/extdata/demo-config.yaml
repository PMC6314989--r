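# End-to-end demo: simulate a moderately abnormal study and quantify it.
seed: 42
output_dir: demo-output
phantom:
  shape: [64, 64, 32]
  true_sbr: 2.0
  psf_fwhm_mm: 10
  noise: poisson
extraction:
  standard_volume_ml: 11.2
  connectivity: 26
tb:
  radii_mm: [26, 36]
  thickness_mm: 44
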