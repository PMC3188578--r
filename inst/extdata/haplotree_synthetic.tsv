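name	parent	mutations	macro
root	-	-	N
M	root	700,783,866	M
N-a	root	949,1032,1115	
R	root	1198,1281,1364	R
M-a	M	1447,1530,1613	
M-b	M	1696,1779,1862	
M-c	M	1945,2028,2111	
D	M-a	2194,2277,2360	
M7	M-a	2443,2526,2609	
D-a	D	2692,2775,2858	
D-b	D	2941,3024,3107	
D4	D-a	3190,3273,3356	
D-a2	D-a	3439,3522,3605	
D4a	D-a2	3688,3771,3854	
D4j	D-a2	3937,4020,4103	
D4h	D-a2	4186,4269,4352	
D-c	D-b	4435,4518,4601	
D5	D-b	4684,4767,4850	
D6	D-b	4933,5016,5099	
D4b2b	D-c	5182,5265,5348	
D4b2b1	D-c	5431,5514,5597	
D5a2a	D5	5680,5763,5846	
D5b	D5	5929,6012,6095	
M7a1a	M7	6178,6261,6344	
M7b1'2'4	M7	6427,6510,6593	
M7c	M7	6676,6759,6842	
M-d	M-b	6925,7008,7091	
M-e	M-b	7174,7257,7340	
C	M-d	7423,7506,7589	
Z	M-d	7672,7755,7838	
M8	M-d	7921,8004,8087	
M9	M-e	8170,8253,8336	
M10	M-e	8419,8502,8585	
M11	M-e	8668,8751,8834	
G	M-c	8917,9000,9083	
M12	M-c	9166,9249,9332	
M33	M-c	9415,9498,9581	
G2a1	G	9664,9747,9830	
G1	G	9913,9996,10079	
A	N-a	10162,10245,10328	
N9	N-a	10411,10494,10577	
N10	N-a	10660,10743,10826	
N9a	N9	10909,10992,11075	
N9b	N9	11158,11241,11324	
R-a	R	11407,11490,11573	
R-b	R	11656,11739,11822	
R-c	R	11905,11988,12071	
B	R-a	12154,12237,12320	
U	R-a	12403,12486,12569	
HV	R-a	12652,12735,12818	
B-a	B	12901,12984,13067	
B-b	B	13150,13233,13316	
B4	B-a	13399,13482,13565	
B4a	B-a	13648,13731,13814	
B4b	B-b	13897,13980,14063	
B5	B-b	14146,14229,14312	
R9	R-c	14395,14478,14561	
R11	R-c	14644,14727,14810	
F	R-b	14893,14976,15059	
F3	R-b	15142,15225,15308	
F1a1'4	F	15391,15474,15557	
F2	F	15640,15723,15806	
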