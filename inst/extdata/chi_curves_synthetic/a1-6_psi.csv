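"angle","energy"
-180,0
-170,0.0424
-160,0.166
-150,0.3608
-140,0.6113
-130,0.8981
-120,1.2
-110,1.496
-100,1.7675
-90,2
-80,2.1843
-70,2.3168
-60,2.4
-50,2.4408
-40,2.4498
-30,2.4392
-20,2.4212
-10,2.4059
0,2.4
10,2.4059
20,2.4212
30,2.4392
40,2.4498
50,2.4408
60,2.4
70,2.3168
80,2.1843
90,2
100,1.7675
110,1.496
120,1.2
130,0.8981
140,0.6113
150,0.3608
160,0.166
170,0.0424
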