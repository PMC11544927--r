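# Example run configuration: 40 nm gold nanoparticle diffusing in water,
# 100 kHz acquisition, focal plane 3.2 um above the coverslip.
optics:
  wavelength: 515
  numerical_aperture: 1.4
  n_medium: 1.33
  n_glass: 1.52696
  n_oil: 1.51833
  t_glass_um: 170
  focal_plane_z_um: 3.2
  pixel_size: 101.5625
camera:
  full_well: 23200
  frame_rate: 1.0e5
particle:
  diameter: 40
  n_frames: 2000
tracking:
  image_size: 128
  z_min: 0
  z_max_um: 6.5
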