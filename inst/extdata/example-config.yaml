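# Example CortexQuant run configuration (see ?runConfig for defaults).
seed: 1
pixel_size: 0.25        # um/px
band_width: 5           # um, cortical band
region: cortex          # cortex | whole_cell
segmentation: truth     # truth | snake
simulate:
  n_cells: 12
  mix:
    bipolar: 0.5
    monopolar_toward: 0.5
  distances: [1, 2, 3, 5]
  tissue: somite
noise:
  shot: true
  read_sigma: 2
  offset: 4
  texture_cv: 0.15
  texture_scale: 3
enrichment:             # signal-channel multiplier in the cortical band
  NSB: 1.5
  ANTI: 1.0
  ANT: 1.0
  POST: 1.0
puncta:
  enabled: false
  rate: {NSB: 0, ANTI: 0, ANT: 0, POST: 0}
stats:
  scheme: class
  value: ratio
  distance_edges: [2, 5]
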