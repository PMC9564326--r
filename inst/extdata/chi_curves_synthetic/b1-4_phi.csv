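"angle","energy"
-180,4.355
-170,4.3142
-160,4.2305
-150,4.1341
-140,4.0524
-130,4.0061
-120,4.0061
-110,4.0524
-100,4.1341
-90,4.2305
-80,4.3142
-70,4.355
-60,4.3237
-50,4.1971
-40,3.9606
-30,3.612
-20,3.1618
-10,2.6333
0,2.0607
10,1.4858
20,0.9539
30,0.5089
40,0.1887
50,0.0213
60,0.0213
70,0.1887
80,0.5089
90,0.9539
100,1.4858
110,2.0607
120,2.6333
130,3.1618
140,3.612
150,3.9606
160,4.1971
170,4.3237
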