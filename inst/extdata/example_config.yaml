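# example run configuration for archgait::read_config_yaml()
scenarios:
- ARCHED
- FLATFOOT
- FLATFOOT_TT
- FLATFOOT_TT_IMPLANT
out_dir: archgait_out
calibrate: true
target_mass_kg: 82.0
tol_bw: 0.02
seed: 1
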