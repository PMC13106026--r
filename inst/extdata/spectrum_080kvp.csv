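# kvp=80 filtration_mm_al=4
"energy_keV","value"
20,0.0730733672781537
21,0.109117636530133
22,0.151257510779555
23,0.197571111346533
24,0.245981763914772
25,0.294529051494753
26,0.341536210368741
27,0.385685923400505
28,0.426029656127145
29,0.461956142325041
30,0.493139503585635
31,0.512493590108206
32,0.527922386465254
33,0.539651347684615
34,0.547943480978845
35,0.553081346936813
36,0.555353664654981
37,0.55504567395933
38,0.552432474113301
39,0.547774662609431
40,0.541315711557518
41,0.529966252011789
42,0.517785694555343
43,0.50490257684193
44,0.491431630583461
45,0.477474983409139
46,0.463123316685132
47,0.448456961449718
48,0.433546922240628
49,0.418455824001532
50,0.403238781019583
51,0.386754190437676
52,0.370429196973547
53,0.354279240365578
54,0.338317192522595
55,0.322553675385907
56,0.306997340837852
57,0.29165511718742
58,0.276532426231343
59,0.261633374414507
60,0.246960921192184
61,0.232029618369348
62,0.217415255961848
63,0.20310960443098
64,0.189104584590421
65,0.175392279204343
66,0.161964941834457
67,0.14881500336182
68,0.135935076546936
69,0.123317958938639
70,0.110956634397049
71,0.0988442734572466
72,0.0869742327273969
73,0.0753400534868196
74,0.0639354596254024
75,0.0527543550450825
76,0.0417908206264226
77,0.0310391108481156
78,0.020493650134232
79,0.0101490289928365
80,0
81,0
82,0
83,0
84,0
85,0
86,0
87,0
88,0
89,0
90,0
91,0
92,0
93,0
94,0
95,0
96,0
97,0
98,0
99,0
100,0
101,0
102,0
103,0
104,0
105,0
106,0
107,0
108,0
109,0
110,0
111,0
112,0
113,0
114,0
115,0
116,0
117,0
118,0
119,0
120,0
121,0
122,0
123,0
124,0
125,0
126,0
127,0
128,0
129,0
130,0
131,0
132,0
133,0
134,0
135,0
136,0
137,0
138,0
139,0
140,0
141,0
142,0
143,0
144,0
145,0
146,0
147,0
148,0
149,0
150,0
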