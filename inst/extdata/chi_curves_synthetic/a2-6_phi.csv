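"angle","energy"
-180,3.45
-170,3.3411
-160,3.159
-150,2.9
-140,2.5686
-130,2.1782
-120,1.75
-110,1.3114
-100,0.8935
-90,0.5278
-80,0.2429
-70,0.062
-60,0
-50,0.062
-40,0.2429
-30,0.5278
-20,0.8935
-10,1.3114
0,1.75
10,2.1782
20,2.5686
30,2.9
40,3.159
50,3.3411
60,3.45
70,3.4969
80,3.4981
90,3.4722
100,3.4379
110,3.4104
120,3.4
130,3.4104
140,3.4379
150,3.4722
160,3.4981
170,3.4969
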