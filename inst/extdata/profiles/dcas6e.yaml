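# Primed acquisition with cas6e deleted (KD599-like): weakest strand bias,
# highest derived-spacer emission.
name: dcas6e
mode: primed
n_events: 20000
p_aag_recognition: 0.98
p_derived: 0.0786
p_invert_given_derived: 0.5
shift_window: 5
strand_bias: 0.72
hotspot_dispersion: 1.0
error_rate: 0.0
seed: 1
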