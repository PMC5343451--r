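pet	carnivore_richness	precip_wet	unvegetated	agriculture	precip_dry	forest	K	logL
1	1	1	1	1	1	0	10	-108.33
1	1	1	1	1	1	1	11	-108.32
1	1	1	1	1	0	0	9	-111.98
1	1	1	1	1	0	1	10	-111.56
1	1	1	1	0	1	0	8	-114.65
1	1	1	1	0	1	1	9	-114.58
1	1	1	0	1	1	0	9	-114.60
1	1	1	0	1	1	1	10	-113.93
1	1	1	0	1	0	1	9	-116.95
1	1	1	1	0	0	0	7	-119.64
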