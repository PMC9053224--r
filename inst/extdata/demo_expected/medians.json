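{"within_side_effect":{"median":0.58463819,"n_pairs":264},"within_medication":{"median":0.27402244,"n_pairs":150},"across":{"median":0.27940297,"n_pairs":1320}}
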