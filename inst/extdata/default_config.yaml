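resolution_cutoff: 2.5
identity_threshold: 0.4
sse_min:
  E: 2
  G: 3
  H: 4
n_flank: 2
hetero_cutoff: 6.0
ramachandran:
- code: a
  phi_min: -160.0
  phi_max: -20.0
  psi_min: -90.0
  psi_max: 50.0
- code: b
  phi_min: -180.0
  phi_max: -20.0
  psi_min: 50.0
  psi_max: 180.0
- code: b
  phi_min: -180.0
  phi_max: -20.0
  psi_min: -180.0
  psi_max: -150.0
- code: t
  phi_min: -180.0
  phi_max: -160.0
  psi_min: -90.0
  psi_max: 50.0
- code: p
  phi_min: -180.0
  phi_max: -20.0
  psi_min: -150.0
  psi_max: -90.0
- code: g
  phi_min: -20.0
  phi_max: 20.0
  psi_min: -180.0
  psi_max: 180.0
- code: l
  phi_min: 20.0
  phi_max: 160.0
  psi_min: -50.0
  psi_max: 90.0
- code: e
  phi_min: 20.0
  phi_max: 180.0
  psi_min: 90.0
  psi_max: 180.0
- code: e
  phi_min: 20.0
  phi_max: 180.0
  psi_min: -180.0
  psi_max: -90.0
- code: t
  phi_min: 20.0
  phi_max: 180.0
  psi_min: -90.0
  psi_max: -50.0
- code: t
  phi_min: 160.0
  phi_max: 180.0
  psi_min: -50.0
  psi_max: 90.0
cutoffs:
  distance: 2.0
  hoist: 30.0
  packing: 30.0
  meridian: 45.0
kernel_widths:
  distance: 1.0
  hoist: 15.0
  packing: 15.0
  meridian: 22.5
ds:
  min_cluster_size: 3
mcl:
  inflation: 2.0
  expansion: 2.0
  prune: 1.0e-05
  max_iter: 100.0
  tol: 1.0e-08
  self_loop: 1.0
  min_cluster_size: 3
length_categories:
- label: S
  min: 0.0
  max: 4.0
- label: M
  min: 4.0
  max: 9.0
- label: L
  min: 9.0
  max: 19.0
- label: XL
  min: 19.0
  max: 1.0e+09
consensus_threshold: 0.5
seed: 1
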