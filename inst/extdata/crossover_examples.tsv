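patient	day	before	during	after
1	1	210	193	203
1	2	173	135	167
1	3	116	170	149
2	1	146	187	132
2	2	181	103	167
2	3	156	151	159
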