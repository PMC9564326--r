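"angle","energy"
-180,3.6
-170,3.7081
-160,3.7687
-150,3.7954
-140,3.8024
-130,3.8013
-120,3.8
-110,3.8013
-100,3.8024
-90,3.7954
-80,3.7687
-70,3.7081
-60,3.6
-50,3.4329
-40,3.1998
-30,2.9
-20,2.5399
-10,2.1332
0,1.7
10,1.2655
20,0.8577
30,0.5046
40,0.2316
50,0.059
60,0
70,0.059
80,0.2316
90,0.5046
100,0.8577
110,1.2655
120,1.7
130,2.1332
140,2.5399
150,2.9
160,3.1998
170,3.4329
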