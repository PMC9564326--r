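"angle","energy"
-180,2.2094
-170,1.87
-160,1.5
-150,1.1226
-140,0.7641
-130,0.451
-120,0.2074
-110,0.0529
-100,0
-90,0.0529
-80,0.2074
-70,0.451
-60,0.7641
-50,1.1226
-40,1.5
-30,1.87
-20,2.2094
-10,2.5
0,2.7303
10,2.8961
20,3
30,3.051
40,3.0622
50,3.049
60,3.0265
70,3.0074
80,3
90,3.0074
100,3.0265
110,3.049
120,3.0622
130,3.051
140,3
150,2.8961
160,2.7303
170,2.5
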