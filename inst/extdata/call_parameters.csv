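"species","n_recordings","notes_min","notes_max","harmonics_min","harmonics_max","note_s_mean","note_s_sd","internote_s_mean","internote_s_sd","peak_time_s_mean","dominant_hz_mean","initial_hz_mean","final_hz_mean","freq_change_hz_mean","second_harmonic_hz_mean"
"jimenezi",2,1,2,4,4,0.182,0.035,0.297,0.088,0.091,2894.58,2789.89,2976.56,187.5,5373.79
"phoxocephalus",2,3,9,4,5,0.154,0.03,0.135,0.035,0.077,2578.12,2452.15,2586.91,134.77,4532.23
"totoroi",2,2,6,3,7,0.125,0.038,0.339,0.038,0.063,2569.65,2550.96,2619.88,68.92,4714.43
"verrucolatus",2,1,1,4,7,0.433,0.037,NA,NA,0.216,2114.08,1837.5,2231.25,393.75,4171.89
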