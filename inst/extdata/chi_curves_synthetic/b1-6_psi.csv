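"angle","energy"
-180,0
-170,0.0348
-160,0.1365
-150,0.2974
-140,0.5053
-130,0.745
-120,1
-110,1.2536
-100,1.4909
-90,1.7
-80,1.8729
-70,2.006
-60,2.1
-50,2.1592
-40,2.1906
-30,2.2026
-20,2.2038
-10,2.2014
0,2.2
10,2.2014
20,2.2038
30,2.2026
40,2.1906
50,2.1592
60,2.1
70,2.006
80,1.8729
90,1.7
100,1.4909
110,1.2536
120,1
130,0.745
140,0.5053
150,0.2974
160,0.1365
170,0.0348
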