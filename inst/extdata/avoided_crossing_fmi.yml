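# Example run configuration: FMi surface hopping on the shipped
# avoided-crossing preset, compared against the exact grid propagation with
# `surfhop compare --config <this file>`.
model: avoided_crossing_2s
integrator:
  dt_fs: 0.1
  t_max_fs: 35.0
  n_substeps: 51
decoherence:
  variant: fmi
  eta: 1.0e-4
ensemble:
  n_traj: 500
  seed: 7
  e_d_ev: 1.0
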