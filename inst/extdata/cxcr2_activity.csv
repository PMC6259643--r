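compound_id,source_table,ic50,unit,pic50_printed
1,1,0.07,uM,7.14
2,1,0.17,uM,6.77
3,1,0.06,uM,7.19
4,1,1.30,uM,5.89
5,1,1.40,uM,5.85
6,1,0.22,uM,6.66
7,1,0.26,uM,6.58
8,1,0.09,uM,7.06
9,1,0.16,uM,6.80
10,1,0.02,uM,7.72
11,1,0.25,uM,6.60
12,1,0.64,uM,6.19
13,1,0.12,uM,6.92
14,1,0.14,uM,6.85
15,1,0.40,uM,6.40
16,1,0.52,uM,6.28
17,1,0.05,uM,7.30
18,1,0.12,uM,6.92
19,1,0.07,uM,7.18
20,1,1.10,uM,5.96
21,1,1.10,uM,5.96
22,1,0.88,uM,6.05
23,1,0.26,uM,6.58
24,1,0.06,uM,7.24
25,1,0.02,uM,7.62
26,2,0.005,nM,8.30
27,2,0.006,nM,8.24
28,2,0.004,nM,8.39
29,2,0.005,nM,8.33
30,2,0.005,nM,8.32
31,2,0.017,nM,7.76
32,2,0.007,nM,8.17
33,2,0.003,nM,8.55
34,2,0.094,nM,7.03
35,2,0.171,nM,6.77
36,2,0.049,nM,7.31
37,2,0.15,nM,6.82
38,2,0.058,nM,7.24
39,2,0.087,nM,7.06
40,2,0.0045,nM,8.35
41,2,0.005,nM,8.30
42,2,0.009,nM,8.02
43,2,0.008,nM,8.09
44,2,0.008,nM,8.12
45,2,0.003,nM,8.46
46,2,0.016,nM,7.78
47,2,8.6,nM,8.06
48,2,10.9,nM,7.96
49,2,9.8,nM,8.01
50,2,9.8,nM,8.01
51,2,7.5,nM,8.12
52,2,8.2,nM,8.10
53,2,8.0,nM,8.10
54,2,5.8,nM,8.24
55,2,6.2,nM,8.21
56,2,6.2,nM,8.21
57,2,21,nM,7.68
58,2,50,nM,7.30
59,3,906,nM,6.04
60,3,63,nM,7.20
61,3,10,nM,8.00
62,3,114,nM,6.94
63,3,7,nM,8.15
64,3,12,nM,7.92
65,3,25,nM,7.60
66,3,6,nM,8.22
67,3,22,nM,7.66
68,3,57,nM,7.24
69,3,22,nM,7.66
70,3,320,nM,6.49
71,3,860,nM,6.07
72,3,10900,nM,4.96
73,3,200,nM,6.70
74,3,9.3,nM,8.03
75,3,39,nM,7.49
76,4,130,nM,6.87
77,4,400,nM,6.40
78,4,460,nM,6.34
79,4,90,nM,7.05
80,4,32,nM,7.49
81,4,280,nM,6.55
82,4,1000,nM,6.00
83,5,2400,nM,5.62
84,5,4400,nM,5.36
85,5,7700,nM,5.11
86,5,4200,nM,5.38
87,5,3500,nM,5.46
88,5,3500,nM,5.46
89,5,2800,nM,5.55
90,5,2300,nM,5.64
91,5,2000,nM,5.70
92,5,2000,nM,5.70
93,5,1400,nM,5.85
94,5,1400,nM,5.85
95,5,1000,nM,6.00
96,5,890,nM,6.05
97,5,830,nM,6.08
98,5,800,nM,6.10
99,5,670,nM,6.17
100,5,450,nM,6.35
101,5,410,nM,6.39
102,5,350,nM,6.46
103,5,350,nM,6.46
104,5,10000,nM,5.00
105,5,4200,nM,5.38
106,5,730,nM,6.14
107,5,300,nM,6.52
108,5,170,nM,6.77
109,5,92,nM,7.04
110,5,28,nM,7.55
111,6,160,nM,6.80
112,6,4,nM,8.40
113,6,13,nM,7.89
114,6,630,nM,6.20
115,6,7,nM,8.15
116,6,280,nM,6.55
117,6,140,nM,6.85
118,6,280,nM,6.55
119,6,850,nM,6.07
120,6,5,nM,8.30
121,6,350,nM,6.46
122,6,16,nM,7.80
123,6,2,nM,8.70
124,6,45,nM,7.35
125,6,2500,nM,5.60
126,6,220,nM,6.66
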