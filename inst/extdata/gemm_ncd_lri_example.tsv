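disease	age_group	theta	theta_se	alpha	mu	nu
NCD+LRI	25+	0.1430	0.01807	1.6	15.5	36.8
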