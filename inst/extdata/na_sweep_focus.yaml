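scenario: na_sweep_focus
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
  spheres:
  - center:
    - 0.0
    - 2.0
    - 125.0
    diameter: 20.0
    index: 1.59
    fluorescent: no
sweep:
  na_x_values:
  - 0.03
  - 0.06
  - 0.09
  - 0.12
  - 0.15
  - 0.18
  - 0.21
  - 0.24
  na_y_values:
  - 0.0
  - 0.03
  - 0.06
  - 0.09
  - 0.12
  - 0.15
  - 0.18
  - 0.21
  - 0.24
  metric: focus_intensity
output_dir: '.'

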