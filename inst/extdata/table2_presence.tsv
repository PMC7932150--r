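region	n_present
mpa_hotspot	53
mpa_knysna	60
greater_mpa	69
sea_dominion	70
study_area	73
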