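drug,total,serious,not_serious,seriousness_na,female,male,sex_na,age_under_18,age_18_65,age_66_plus,age_na
L03AB07,3097,349,2378,370,2271,804,22,41,1666,19,1313
L03AB08,541,80,271,190,391,138,12,2,509,16,15
L03AB13,558,66,461,31,373,102,83,0,317,3,238
L03AX13,2047,446,1562,39,1588,428,31,14,1617,41,375
L04AA34,1226,359,851,16,853,357,16,2,1076,7,141
L04AA40,72,13,59,0,57,15,0,0,59,0,13
L04AX07,1326,326,979,21,962,339,25,5,1067,18,236
L04AA27,2652,1112,1418,122,1805,815,32,13,2391,19,229
L04AA23,1265,496,741,28,923,317,25,13,1054,48,150
L04AA36,340,138,200,2,188,143,9,0,286,8,46
L04AA31,756,236,506,14,538,195,23,0,575,24,157
Total,13880,3621,9426,833,9949,3653,278,90,10617,203,2913
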