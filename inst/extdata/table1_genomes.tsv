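strain	accession	status	length_mbp	subspecies
ATCC 15697T	NC_011593	complete	2.83	infantis
EK3	JNWC00000000	draft	2.56	infantis
AGR2137	ATWX00000000	draft	2.27	suis
JDM301	NC_014169	complete	2.48	suis
LMG 21814T	JGZA00000000	draft	2.34	suis
12_1_47BFAA	NZ_ADCN00000000	draft	2.40	longum
157F	NC_015052	complete	2.40	longum
1-5B	JNVX00000000	draft	2.37	longum
17-1B	JNVZ00000000	draft	2.47	longum
1-6B	AJTF00000000	draft	2.69	longum
2-2B	AJTJ00000000	draft	2.63	longum
35B	AJTI00000000	draft	2.51	longum
44B	AJTM00000000	draft	2.56	longum
72B	JNWA00000000	draft	2.37	longum
7-1B	JNVY00000000	draft	2.41	longum
ATCC 55813	ACHI00000000	draft	2.37	longum
BBMN68	NC_014656	complete	2.27	longum
CCUG 52486	NZ_ABQQ00000000	draft	2.45	longum
CECT 7347	NZ_CALH00000000	draft	2.33	longum
DJO10A	NC_010816	complete	2.38	longum
E18	AUYD00000000	draft	2.37	longum
F8	NC_021008	draft	2.37	longum
EK5	JNWC00000000	draft	2.23	longum
EK13	JNWD00000000	draft	2.47	longum
JCM 1217T	NC_015067	complete	2.39	longum
KACC 91563	NC_017221	complete	2.39	longum
NCC2705	NC_004307	complete	2.26	longum
VMKB44	JRWN00000000	draft	2.51	longum
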