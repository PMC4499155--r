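# Naive (non-primed) acquisition: no PAM preference beyond ~50%, no strand
# bias, no derived emissions.
name: naive
mode: naive
n_events: 20000
p_aag_recognition: 0.50
p_derived: 0.0
p_invert_given_derived: 0.5
shift_window: 5
strand_bias: 0.50
hotspot_dispersion: 1.0
error_rate: 0.0
seed: 1
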