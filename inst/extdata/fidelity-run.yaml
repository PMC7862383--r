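# End-to-end fidelity run: hex-packed checkerboard test article
# (Ø 500 um posts nested in an open lattice at 1000 um pitch) on a
# 300 um dye-free base, imaged at 5 um/px with 15 um per-axis
# post-placement jitter. All lengths in um.
seed: 1
design:
  type: checkerboard
  post_diameter: 500
  pitch: 1000
  rows: 8
  cols: 8
  base_thickness: 300
  n_base_layers: 1
  feature_thickness: 100
projector:
  pixel_pitch: 50
  resolution: [1280, 800]
  intensity: 16.5
  wavelength: 405
dose_model:
  entries:
    "200": 60
    "300": 120
  reference_intensity: 10
  interpolate: true
schedule:
  rinse_policy: strict
imaging:
  pixel_size: 5
  blur_sigma: 2
  noise_sd: 0.01
  background: 0.05
  channels:
    post: 1
    lattice: 2
fidelity:
  placement_jitter_sd: 15
  diameter_error_sd: 0
  edge_roughness: 0
morphometry:
  threshold: 50
  segmentation: otsu
  min_area: 2000
outdir: mmsla-out
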