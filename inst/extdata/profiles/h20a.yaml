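# Primed acquisition with catalytically dead Cas6e (H20A-like).
# strand_bias and p_derived interpolate the ordering between the kd263 and
# dcas6e endpoints; no per-sample figure is available.
name: h20a
mode: primed
n_events: 20000
p_aag_recognition: 0.98
p_derived: 0.066
p_invert_given_derived: 0.5
shift_window: 5
strand_bias: 0.80
hotspot_dispersion: 1.0
error_rate: 0.0
seed: 1
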