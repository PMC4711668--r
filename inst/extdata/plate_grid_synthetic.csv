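,1,2,3,4,5,6,7,8,9,10,11,12
A,1.0512,1.152,1.1156,1.1234,1.1542,1.133,1.1395,1.1052,1.0786,1.1026,1.1046,1.1153
B,1.1139,1.1845,1.0639,1.0271,1.1589,1.0625,1.1032,1.1581,1.0227,1.1228,1.1723,1.0709
C,1.1016,1.072,1.0389,1.0686,1.0939,1.1478,1.0595,1.0831,1.0741,1.1362,1.1493,1.1198
D,1.1098,1.1128,1.1512,1.0627,1.1265,1.1037,1.0699,1.0518,1.0947,1.0616,1.0997,1.1279
E,0.1671,0.0954,0.1413,0.0778,0.1048,0.1756,0.0864,0.1186,0.0974,0.0909,0.0722,0.1353
F,0.0821,0.0976,0.1175,0.0931,0.1605,0.1211,0.155,0.0734,0.1859,0.0898,0.046,0.1035
G,0.1195,-0.0365,0.0696,0.1678,0.1265,0.079,0.0968,0.0853,0.1476,0.1628,0.1937,0.1739
H,0.0685,0.0987,0.0585,0.0919,0.0927,0.1356,0.0954,0.2448,0.0836,0.1047,0.1038,0.1492
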