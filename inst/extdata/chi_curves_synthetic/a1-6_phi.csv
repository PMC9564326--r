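"angle","energy"
-180,3.4753
-170,3.2764
-160,3
-150,2.6512
-140,2.244
-130,1.8
-120,1.3472
-110,0.9169
-100,0.5412
-90,0.2489
-80,0.0635
-70,0
-60,0.0635
-50,0.2489
-40,0.5412
-30,0.9169
-20,1.3472
-10,1.8
0,2.244
10,2.6512
20,3
30,3.2764
40,3.4753
50,3.6
60,3.6612
70,3.6747
80,3.6588
90,3.6318
100,3.6088
110,3.6
120,3.6088
130,3.6318
140,3.6588
150,3.6747
160,3.6612
170,3.6
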