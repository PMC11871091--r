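# Default HU threshold scheme for the seven-tissue protocol.
# Intervals are half-open [low, high); see ?threshold_scheme.
cortical_min: 300
trabecular_range: [150, 300]
hbm_range: [50, 150]
mat_max: 50
muscle_range: [-30, 500]
fat_max: -30
air_cutoff: -200
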