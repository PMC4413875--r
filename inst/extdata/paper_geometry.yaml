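# Default study-condition configuration for the synthetic 2D-crystal
# cryo-ET workflow.  All lengths in Angstrom, angles in degrees.
phantom:
  head_diameter: 100        # 10 nm catalytic head
  head_height: 150          # head centre 15 nm above the membrane midplane
  central_stalk_radius: 10
  peripheral_stalk_radius: 14
  peripheral_stalk_offset: 52
  cring_radius: 22
  cring_height: 40
  membrane_thickness: 40
  protein_density: 1.0
  lipid_density: 0.5
  box_center_height: 80     # particle reference point above the c-ring midplane
  box: 40                   # phantom / subvolume cube edge, voxels
crystal:
  a: 179.1                  # 2D unit cell
  b: 171.4
  gamma: 94.9
  inclination_theta: 16     # long-axis tilt from the crystal-plane normal
  pair_azimuth_delta: 98.1  # makes theta = 16 produce a 24 deg pair angle
  interface_rotation: 90    # in-plane rotation between opposite-face partners
  kink_kappa: 43            # membrane kink at each particle row
  interface_offset: 45      # separation of apposed c-rings along the row
  jitter_sigma_xy: 2        # positional disorder (A)
  jitter_sigma_angle: 1.5   # angular disorder (deg)
  n_cells: [4, 4]           # desk-scale 4 x 4 cells -> 64 particles
tomogram:
  nz: 96
  ny: 160
  nx: 160
  voxel_size: 6.66          # tomographic sampling, A/voxel
tilt:
  min_angle: -60            # single-axis series +/-60 deg
  max_angle: 60
  step: 1.5                 # 81 projections
  snr: 1.0                  # noise sd = projection signal sd / snr
average:
  max_xy_rot: 45            # off-axis rotation bound, deg
  max_shift: 12             # translation bound per axis, voxels
  mask_radius: 75           # soft real-space mask on reference and particles, A
  mask_shape: cylinder      # z-cylinder: keeps own wedge ghosts, excludes neighbours
  highpass: 180             # scoring high-pass, A (suppresses broad slab correlation)
  wedge_theta: 60
  bootstrap: seed_grow      # reference bootstrap (see refine_gold_standard)
  bootstrap_resolution: 24  # A
  schedule:                 # binning, low-pass (A), angular step, iterations
    - {binning: 2, resolution: 60, step: 15, iterations: 1}
    - {binning: 2, resolution: 40, step: 7.5, iterations: 1}
    - {binning: 1, resolution: 24, step: 15, iterations: 1}
    - {binning: 1, resolution: 24, step: 4, iterations: 2, max_shift: 3}
validation:
  randomize_cutoff: 40      # phase-randomisation cutoff, A
  fermi_cutoff: 18          # final-map Fermi filter, A
  fermi_temperature: 0.002  # reciprocal pixels
  fsc_threshold: 0.5
geometry:
  same_face_cutoff: 130     # pair assignment, A
  cross_face_cutoff: 80     # interface assignment, A
  kink_band: 55             # membrane ridge z search band, A
  kink_vertex_window: 12    # x half-window for vertex-height estimates, A
  kink_sigma: 8             # Gaussian smoothing before ridge tracing, A
  head_band: [100, 220]     # head segmentation band above the midplane, A
crystallography:
  resolution_limit: 30      # projection-map band limit, A
  z_levels:                 # slice-band centres relative to the midplane, A
    head: 150
    stalk: 80
    membrane: 0
  level_halfwidth: 23       # +/- band converted to z-slices
seed: 7
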