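# kvp=140 filtration_mm_al=4
"energy_keV","value"
20,0.146146734556307
21,0.220084724526879
22,0.307730797792887
23,0.405540702237621
24,0.509533653823456
25,0.615833471307211
26,0.72102088855623
27,0.822311497061455
28,0.917602336273851
29,1.00543395682509
30,1.0849069078884
31,1.14003676166927
32,1.18782536954682
33,1.22856796175008
34,1.26265236921212
35,1.29052314285256
36,1.31265411645723
37,1.32952800971654
38,1.34162172284659
39,1.34939612008665
40,1.35328927889379
41,1.34529894741454
42,1.33534205437957
43,1.32366351226127
44,1.31048434822256
45,1.29600352639623
46,1.28039975789419
47,1.26383325499466
48,1.24644740144181
49,1.22837032206901
50,1.20971634305875
51,1.18693527410183
52,1.16420604763115
53,1.14156644117797
54,1.11904917526705
55,1.09668249631208
56,1.07449069293248
57,1.05249455332852
58,1.03071177049864
59,1.0091573013131
60,0.987843684768735
61,0.964754729009395
62,0.942132775834673
63,0.919967031834439
64,0.898246776804501
65,0.876961396021714
66,0.856100406839271
67,0.835653480416375
68,0.815610459281614
69,0.795961371331217
70,0.776696440779343
71,0.757806096505557
72,0.739280978182874
73,0.721111940516702
74,0.703290055879426
75,0.685806615586072
76,0.668653130022762
77,0.65182132781043
78,0.635303154161193
79,0.619090768563023
80,0.60317654190959
81,0.586998313875366
82,0.57115192692815
83,0.555627214160334
84,0.540414419654286
85,0.525504178005427
86,0.510887495048957
87,0.496555729709299
88,0.482500576897441
89,0.468714051386904
90,0.455188472604185
91,0.441916450274237
92,0.428890870865867
93,0.416104884785918
94,0.403551894274757
95,0.391225541958975
96,0.379119700020309
97,0.367228459942681
98,0.35554612280187
99,0.344067190064803
100,0.332786354867697
101,0.321561469891975
102,0.310536913119749
103,0.299707268686345
104,0.289067316091786
105,0.278612021416756
106,0.268336529010288
107,0.258236153619811
108,0.248306372936215
109,0.238542820528574
110,0.228941279144873
111,0.219497674356752
112,0.210208068527765
113,0.201068655086033
114,0.192075753083476
115,0.183225802024977
116,0.174515356951923
117,0.165941083765615
118,0.157499754776946
119,0.149188244469645
120,0.141003525465186
121,0.132942664678218
122,0.125002819652071
123,0.117181235064538
124,0.109475239394754
125,0.101882241742543
126,0.0943997287921255
127,0.0870252619125919
128,0.0797564743879688
129,0.0725910687701649
130,0.0655268143484554
131,0.0585615447295476
132,0.051693155522614
133,0.044919602124002
134,0.0382388975966347
135,0.0316491106393989
136,0.025148363642084
137,0.0187348308216834
138,0.0124067364361023
139,0.00616235307153826
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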