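drug,total,serious,not_serious,seriousness_na,female,male,sex_na,age_under_18,age_18_65,age_66_plus,age_na
L03AB07,197,30,136,31,130,65,2,0,168,1,28
L03AB08,87,22,48,17,68,18,1,0,81,3,3
L03AB13,38,7,27,4,28,10,0,0,33,0,5
L03AX13,103,25,70,8,73,27,3,1,96,2,4
L04AA34,58,15,41,2,38,20,0,0,55,0,3
L04AA40,31,5,26,0,29,2,0,0,31,0,0
L04AX07,124,32,89,3,95,28,1,0,114,0,10
L04AA27,172,59,108,5,131,40,1,0,166,0,6
L04AA23,212,69,138,5,154,55,3,2,192,8,10
L04AA36,13,7,6,0,9,4,0,0,11,1,1
L04AA31,81,23,57,1,52,28,1,0,73,2,6
multiple_suspected,3,3,0,0,2,1,0,0,2,1,0
Total,1119,297,746,76,809,298,12,3,1022,18,76
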