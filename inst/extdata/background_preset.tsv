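node	size
D4h	4
D5b	4
D6	4
M7c	4
C	4
Z	4
M8	4
M9	4
M10	4
M11	4
M12	4
M33	4
G1	4
N9b	4
N10	4
R9	4
R11	4
U	4
HV	4
B4b	4
B5	3
F3	3
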