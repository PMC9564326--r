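"angle","energy"
-180,4.0105
-170,3.7622
-160,3.4135
-150,2.9752
-140,2.469
-130,1.9265
-120,1.3858
-110,0.8881
-100,0.4732
-90,0.1753
-80,0.0198
-70,0.0198
-60,0.1753
-50,0.4732
-40,0.8881
-30,1.3858
-20,1.9265
-10,2.469
0,2.9752
10,3.4135
20,3.7622
30,4.0105
40,4.1595
50,4.2208
60,4.2142
70,4.1647
80,4.0984
90,4.039
100,4.0045
110,4.0045
120,4.039
130,4.0984
140,4.1647
150,4.2142
160,4.2208
170,4.1595
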