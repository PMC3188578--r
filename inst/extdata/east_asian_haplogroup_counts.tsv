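haplogroup	CHB	CHD	CHS	JPT
B4	14	12	5	11
B5	3	1	6	5
N9	7	1	7	10
A	9	7	4	8
R9	2	0	2	0
F	21	11	5	9
R11	2	1	3	0
U	1	1	0	0
HV	1	0	0	0
N10	1	0	0	0
D4	15	10	6	39
D5	11	3	2	3
D6	0	0	1	0
M7	12	9	7	12
C	4	5	1	0
Z	2	1	2	4
M8	3	2	1	2
M9	1	2	0	3
M10	4	1	1	0
M11	1	1	0	0
M12	0	1	1	0
G	7	4	0	12
M33	0	0	1	0
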