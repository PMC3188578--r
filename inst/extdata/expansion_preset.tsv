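haplogroup	n	tmrca_ky
D4	70	26.66
D4b2b	14	12.37
D4b2b1	7	7.5
D4a	12	14.06
D4j	9	17.42
D5a2a	10	14.76
A	28	19.72
N9a	21	16.84
F1a1'4	11	17.71
F2	12	20.92
B4	42	36.24
B4a	10	20.15
G2a1	7	16.97
M7a1a	8	7.21
M7b1'2'4	20	14.62
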