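"angle","energy"
-180,0
-170,0.0393
-160,0.1539
-150,0.334
-140,0.5645
-130,0.8267
-120,1.1
-110,1.3644
-100,1.6022
-90,1.8
-80,1.9495
-70,2.0484
-60,2.1
-50,2.1122
-40,2.0966
-30,2.066
-20,2.0333
-10,2.0089
0,2
10,2.0089
20,2.0333
30,2.066
40,2.0966
50,2.1122
60,2.1
70,2.0484
80,1.9495
90,1.8
100,1.6022
110,1.3644
120,1.1
130,0.8267
140,0.5645
150,0.334
160,0.1539
170,0.0393
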