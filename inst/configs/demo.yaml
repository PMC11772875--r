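# Demo pipeline run on a synthetic scene (no external data needed).
output_dir: demo_out
seed: 11
thresholds:
  min_volume_um3: 0.05
  spot_spot_um: 0.2
  spot_surface_um: 0.1
  surface_surface_um: 0
  spot_diameter_um: 0.2
tracking:
  gate_um: 2
  max_gap: 1
scene:
  field_size_um: [3, 20, 20]
  n_condensates: 30
  association_fraction: 0.3
  organelle:
    geometry: puncta
    n_puncta: 60
    radius_um: 0.25
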