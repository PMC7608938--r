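group	moisture	fat	protein	crude_fiber	ash
LRS	4.9	18.9	37.6	3.2	6.1
HRS	5.4	19.0	38.0	3.1	6.1
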