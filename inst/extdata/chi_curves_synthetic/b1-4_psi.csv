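"angle","energy"
-180,3.2
-170,3.2058
-160,3.2205
-150,3.2356
-140,3.2388
-130,3.2153
-120,3.15
-110,3.0303
-100,2.8477
-90,2.6
-80,2.292
-70,1.9358
-60,1.55
-50,1.1584
-40,0.7875
-30,0.4644
-20,0.2135
-10,0.0545
0,0
10,0.0545
20,0.2135
30,0.4644
40,0.7875
50,1.1584
60,1.55
70,1.9358
80,2.292
90,2.6
100,2.8477
110,3.0303
120,3.15
130,3.2153
140,3.2388
150,3.2356
160,3.2205
170,3.2058
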