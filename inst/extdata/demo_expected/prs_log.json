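{"BMI":{"n_input_stats":400,"n_shared":400,"n_low_info":35,"n_strand_ambiguous":120,"n_retained":245,"n_harmonized":245,"n_index":40,"n_per_threshold":[10,13,15,21,29,33,40,40]},"INSOMNIA":{"n_input_stats":400,"n_shared":400,"n_low_info":35,"n_strand_ambiguous":120,"n_retained":245,"n_harmonized":245,"n_index":40,"n_per_threshold":[12,18,20,27,33,36,40,40]},"HEADACHE":{"n_input_stats":400,"n_shared":400,"n_low_info":35,"n_strand_ambiguous":120,"n_retained":245,"n_harmonized":245,"n_index":40,"n_per_threshold":[13,14,19,24,30,36,40,40]},"MDD":{"n_input_stats":400,"n_shared":400,"n_low_info":35,"n_strand_ambiguous":120,"n_retained":245,"n_harmonized":245,"n_index":40,"n_per_threshold":[12,15,21,26,31,34,39,40]}}
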