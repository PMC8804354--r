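sex	age	height_cm	bmi
male	6	115.5	15.8
male	7	121.0	16.1
male	8	126.5	16.4
male	9	132.0	16.9
male	10	137.5	17.5
male	11	143.0	18.0
male	12	149.5	18.6
male	13	156.5	19.2
male	14	162.5	19.8
male	15	166.5	20.3
male	16	168.5	20.8
male	17	170.0	21.2
male	18	170.5	21.6
female	6	114.5	15.4
female	7	120.5	15.7
female	8	126.0	16.0
female	9	131.5	16.5
female	10	137.5	17.0
female	11	144.0	17.6
female	12	149.5	18.2
female	13	152.5	18.8
female	14	155.0	19.4
female	15	156.5	19.8
female	16	157.0	20.2
female	17	157.5	20.5
female	18	157.5	20.8
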