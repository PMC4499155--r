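# Primed acquisition, intact cas genes and genomic crRNA source (KD263-like).
name: kd263
mode: primed
n_events: 20000
p_aag_recognition: 0.98
p_derived: 0.0398
p_invert_given_derived: 0.5
shift_window: 5
strand_bias: 0.90
hotspot_dispersion: 1.0
error_rate: 0.0
seed: 1
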