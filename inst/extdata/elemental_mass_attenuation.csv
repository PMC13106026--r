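element,energy_keV,mu_rho_cm2_g
H,10,0.3854
H,15,0.3764
H,20,0.3695
H,30,0.3570
H,40,0.3458
H,50,0.3355
H,60,0.3260
H,80,0.3091
H,100,0.2944
H,150,0.2651
H,200,0.2429
C,10,2.373
C,15,0.8071
C,20,0.4420
C,30,0.2562
C,40,0.2076
C,50,0.1871
C,60,0.1753
C,80,0.1610
C,100,0.1514
C,150,0.1347
C,200,0.1229
N,10,3.879
N,15,1.236
N,20,0.6178
N,30,0.3066
N,40,0.2288
N,50,0.1980
N,60,0.1817
N,80,0.1639
N,100,0.1529
N,150,0.1353
N,200,0.1233
O,10,5.952
O,15,1.836
O,20,0.8651
O,30,0.3779
O,40,0.2585
O,50,0.2132
O,60,0.1907
O,80,0.1678
O,100,0.1551
O,150,0.1361
O,200,0.1237
F,10,8.205
F,15,2.492
F,20,1.133
F,30,0.4487
F,40,0.2828
F,50,0.2214
F,60,0.1920
F,80,0.1639
F,100,0.1496
F,150,0.1298
F,200,0.1176
Al,10,26.23
Al,15,7.955
Al,20,3.441
Al,30,1.128
Al,40,0.5685
Al,50,0.3681
Al,60,0.2778
Al,80,0.2018
Al,100,0.1704
Al,150,0.1378
Al,200,0.1223
P,10,41.20
P,15,12.70
P,20,5.500
P,30,1.770
P,40,0.8400
P,50,0.5100
P,60,0.3613
P,80,0.2405
P,100,0.1925
P,150,0.1476
P,200,0.1288
Ca,10,93.41
Ca,15,28.96
Ca,20,12.45
Ca,30,3.931
Ca,40,1.767
Ca,50,0.9936
Ca,60,0.6472
Ca,80,0.3846
Ca,100,0.2819
Ca,150,0.1929
Ca,200,0.1582
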