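impact.group1	impact.group2	sensitivity.group1	sensitivity.group2	group
1	0	0	-6	1
1	0	0	-6	1
1	0	0	-6	1
1	0	0	-6	1
1	0	0	-6	1
1	0	0	-6	1
0	1	-2	0	2
0	1	-2	0	2
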