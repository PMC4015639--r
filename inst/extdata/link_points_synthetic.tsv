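p_isch	p_sten	weight	threshold_label
0.15	0.35	120	0.75
0.25	0.45	200	0.75
0.40	0.55	150	0.75
0.55	0.70	90	0.75
0.70	0.85	60	0.75
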