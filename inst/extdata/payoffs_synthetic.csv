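"id","T","R","P","S"
1,54,44,18,15
2,63,31,23,12
3,62,39,20,13
4,69,41,22,11
5,53,50,30,9
6,64,39,38,16
7,59,50,38,8
8,59,45,32,19
9,57,46,27,1
10,55,33,30,8
11,64,48,37,20
12,65,48,35,20
13,51,38,36,17
14,66,37,20,13
15,68,36,21,6
16,63,39,31,5
17,51,38,35,4
18,60,35,24,14
19,60,47,34,9
20,51,36,21,2
21,59,37,32,13
22,57,40,35,4
23,57,41,30,3
24,69,39,37,16
25,55,45,34,5
26,51,48,28,9
27,59,49,20,17
28,63,41,30,13
29,55,39,21,9
30,64,39,27,13
31,61,39,31,20
32,62,49,36,7
33,50,45,28,0
34,58,31,23,5
35,50,32,21,10
36,50,45,18,7
37,62,45,18,4
38,50,30,23,3
39,60,50,36,15
40,69,45,29,16
41,56,41,24,1
42,59,47,23,5
43,58,35,34,1
44,51,45,37,4
45,57,44,26,3
46,69,39,37,17
47,54,31,29,9
48,56,48,19,7
49,49,41,33,19
50,62,44,31,7
51,58,49,24,3
52,66,32,20,12
53,49,38,35,3
54,62,46,36,5
55,65,44,29,1
56,68,48,38,14
57,67,40,18,2
58,60,47,35,4
59,62,40,21,5
60,57,41,26,16
61,54,46,37,19
62,58,39,34,1
63,53,37,24,12
64,65,43,27,9
65,65,34,25,6
66,61,45,36,17
67,49,44,27,18
68,63,42,25,9
69,68,31,19,15
70,57,35,25,1
71,53,47,25,6
72,57,40,21,20
73,51,36,23,2
74,55,47,35,14
75,52,35,27,1
76,61,45,26,15
77,65,36,34,16
78,51,31,20,2
79,55,47,18,3
80,67,44,35,9
81,69,39,31,9
82,50,49,20,7
83,54,36,32,14
84,51,49,22,12
85,60,43,38,3
86,54,49,21,10
87,69,38,24,11
88,59,41,28,9
89,53,46,32,12
90,66,31,27,5
91,60,32,26,2
92,63,49,38,5
93,59,33,23,20
94,62,50,24,11
95,64,38,30,15
96,59,42,27,7
97,65,36,30,10
98,56,40,22,4
99,68,32,25,14
100,56,39,26,14
101,69,41,24,16
102,57,44,23,15
103,59,50,25,13
104,62,38,32,10
105,49,43,22,10
106,62,34,21,18
107,54,44,20,11
108,65,34,30,18
109,68,36,34,11
110,52,39,36,11
111,66,48,36,6
112,50,38,34,20
113,66,31,30,1
114,59,34,23,13
115,53,40,36,20
116,55,37,35,3
117,68,42,23,5
118,59,37,18,7
119,59,30,27,13
120,67,48,30,8
121,53,39,32,9
122,51,33,32,16
123,68,41,22,15
124,49,32,20,9
125,68,45,33,8
126,53,45,31,17
127,50,30,22,20
128,49,41,22,10
129,59,50,35,12
130,52,41,18,1
131,56,35,21,3
132,64,35,20,8
133,52,46,38,9
134,67,35,27,15
135,64,44,21,2
136,61,39,26,14
137,67,34,25,5
138,60,49,22,8
139,62,32,20,7
140,55,45,24,17
141,58,45,28,19
142,49,30,29,15
143,50,32,23,15
144,66,42,21,15
145,68,42,29,10
146,57,33,20,8
147,62,49,29,10
148,69,38,32,10
149,52,36,29,16
150,62,39,33,14
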