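scenario: bead_field_tiled
preset: scaled
seed: 1
grid:
  nx: 300
  ny: 300
  nz: 740
  dx: 0.5
  dy: 0.5
  dz: 0.5
beam:
  na_x: 0.06
  na_y: 0.06
  wavelength: 0.66
  medium_index: 1.46
detection:
  na: 0.4
  lambda_em: 0.68
  psf_model: gaussian-approx
  slit_width: 20.0
  mode: confocal-line
  pixel_pitch: 0.77
phantom:
  n_background: 1.46
  gel_fluorescent: yes
  random:
    diameter: 6.0
    volume_fraction: 0.002
    seed: 1.0
    min_gap: 1.0
plan:
  mode: DSLM
  scan_step: 2.0
  tile_step: 50.0
  normalize: yes
output_dir: '.'

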