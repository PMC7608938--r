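index	week	group	mean	se
S	3	LRS	104.63	2.44
S	3	HRS	109.42	1.90
expH	3	LRS	16.92	0.79
expH	3	HRS	21.06	0.84
invSimp	3	LRS	10.04	0.51
invSimp	3	HRS	12.34	0.68
J	3	LRS	0.60	0.01
J	3	HRS	0.64	0.01
S	6	LRS	102.85	3.21
S	6	HRS	110.66	2.76
expH	6	LRS	16.98	0.67
expH	6	HRS	20.50	0.66
invSimp	6	LRS	10.34	0.50
invSimp	6	HRS	12.21	0.53
J	6	LRS	0.61	0.01
J	6	HRS	0.64	0.01
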