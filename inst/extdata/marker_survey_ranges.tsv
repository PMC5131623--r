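metric	min	max
variable_n	12	507
bootstrap_mean	26	82
rf_to_reference	4	22
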