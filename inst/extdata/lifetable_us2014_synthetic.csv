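age,qx
0,6.3e-5
1,6.9e-5
2,7.5e-5
3,8.1e-5
4,8.9e-5
5,9.6e-5
6,1.05e-4
7,1.14e-4
8,1.24e-4
9,1.35e-4
10,1.47e-4
11,1.6e-4
12,1.75e-4
13,1.9e-4
14,2.07e-4
15,2.25e-4
16,2.45e-4
17,2.67e-4
18,2.91e-4
19,3.17e-4
20,3.45e-4
21,3.75e-4
22,4.09e-4
23,4.45e-4
24,4.84e-4
25,5.27e-4
26,5.74e-4
27,6.25e-4
28,6.8e-4
29,7.41e-4
30,8.07e-4
31,8.78e-4
32,9.56e-4
33,0.001041
34,0.001133
35,0.001233
36,0.001343
37,0.001462
38,0.001591
39,0.001732
40,0.001886
41,0.002053
42,0.002235
43,0.002433
44,0.002649
45,0.002883
46,0.003139
47,0.003417
48,0.003719
49,0.004049
50,0.004407
51,0.004797
52,0.005221
53,0.005683
54,0.006186
55,0.006733
56,0.007328
57,0.007976
58,0.00868
59,0.009446
60,0.01028
61,0.011187
62,0.012174
63,0.013246
64,0.014413
65,0.015682
66,0.017061
67,0.01856
68,0.02019
69,0.021962
70,0.023887
71,0.025978
72,0.02825
73,0.030717
74,0.033396
75,0.036305
76,0.039461
77,0.042886
78,0.046601
79,0.050628
80,0.054994
81,0.059725
82,0.064848
83,0.070394
84,0.076394
85,0.082883
86,0.089896
87,0.09747
88,0.105644
89,0.114459
90,0.123957
91,0.134183
92,0.14518
93,0.156993
94,0.16967
95,0.183254
96,0.197791
97,0.213323
98,0.229892
99,0.247534
100,0.266282
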