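"angle","energy"
-180,2.8
-170,2.8149
-160,2.8559
-150,2.9124
-140,2.9683
-130,3.0041
-120,3
-110,2.9385
-100,2.8069
-90,2.6
-80,2.3207
-70,1.9808
-60,1.6
-50,1.2043
-40,0.8233
-30,0.4876
-20,0.2248
-10,0.0575
0,0
10,0.0575
20,0.2248
30,0.4876
40,0.8233
50,1.2043
60,1.6
70,1.9808
80,2.3207
90,2.6
100,2.8069
110,2.9385
120,3
130,3.0041
140,2.9683
150,2.9124
160,2.8559
170,2.8149
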