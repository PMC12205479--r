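# SYNTHETIC position probability matrix (one row per position; columns
# A C G T). This is a constructed, informative, auxin-response-element-like
# matrix used to exercise and calibrate PWM scanning; it is NOT an
# empirically derived binding model.
A	C	G	T
0.05	0.08	0.07	0.80
0.06	0.04	0.82	0.08
0.07	0.05	0.09	0.79
0.09	0.76	0.06	0.09
0.11	0.13	0.55	0.21
0.16	0.09	0.61	0.14
0.23	0.27	0.24	0.26
0.12	0.58	0.17	0.13
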