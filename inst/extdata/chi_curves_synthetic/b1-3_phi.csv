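"angle","energy"
-180,4.4013
-170,4.4556
-160,4.4627
-150,4.4439
-140,4.4188
-130,4.4023
-120,4.4023
-110,4.4188
-100,4.4439
-90,4.4627
-80,4.4556
-70,4.4013
-60,4.2797
-50,4.0756
-40,3.7811
-30,3.3976
-20,2.9368
-10,2.4202
0,1.8775
10,1.3444
20,0.8585
30,0.4562
40,0.1687
50,0.019
60,0.019
70,0.1687
80,0.4562
90,0.8585
100,1.3444
110,1.8775
120,2.4202
130,2.9368
140,3.3976
150,3.7811
160,4.0756
170,4.2797
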