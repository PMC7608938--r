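analyte	week	group	mean	se
acetate	3	LRS	2781.2	266.7
acetate	3	HRS	3456.8	269.6
propionate	3	LRS	1289.8	107.8
propionate	3	HRS	1460.8	114.8
butyrate	3	LRS	1369.0	120.9
butyrate	3	HRS	2397.8	183.7
isobutyrate	3	LRS	282.0	25.6
isobutyrate	3	HRS	268.6	20.2
methylbutyrate2	3	LRS	176.8	17.4
methylbutyrate2	3	HRS	169.4	12.0
isovalerate	3	LRS	342.7	29.3
isovalerate	3	HRS	339.1	22.8
acetate	6	LRS	2378.8	240.1
acetate	6	HRS	2681.9	193.1
propionate	6	LRS	1033.1	112.6
propionate	6	HRS	1165.1	92.4
butyrate	6	LRS	1303.8	93.2
butyrate	6	HRS	1842.8	171.6
isobutyrate	6	LRS	281.6	20.1
isobutyrate	6	HRS	250.9	17.7
methylbutyrate2	6	LRS	185.8	17.5
methylbutyrate2	6	HRS	165.8	13.6
isovalerate	6	LRS	350.4	24.2
isovalerate	6	HRS	310.0	20.2
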