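# Demo simulation config for `fifspec.R simulate`:
# a 50/50 (by protomer) monomer/dimer membrane patch at 40 protomers/um^2
# with sparse bright punctae, imaged with the default detector model.
mixture:
  sizes: [1, 2]
  densities: [20, 10]
  q0: 205
psf:
  w_xy: 0.2656
detector:
  offset: 0
  read_noise_sd: 20
  background_mean: 50
  background_sd: 15
punctae:
  count_density: 0.02
  intensity_scale: 10
  radius_um: 0.3
shape_px: [360, 360]
pixel_size_um: 0.06
seed: 1
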