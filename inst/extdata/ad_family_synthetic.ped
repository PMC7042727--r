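FAM1	102	0	0	1	2
FAM1	101	0	0	2	1
FAM1	200	102	101	1	2
FAM1	121	102	101	1	2
FAM1	122	102	101	2	1
FAM1	123	102	101	1	1
FAM1	124	102	101	1	2
FAM1	203	0	0	2	1
FAM1	201	200	203	1	1
FAM1	202	200	203	2	1
FAM1	225	0	0	1	1
FAM1	221	225	122	1	1
FAM1	222	225	122	2	1
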