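material,density_g_cm3,element,mass_fraction
water,1.000,H,0.111898
water,1.000,O,0.888102
air,0.001205,N,0.765000
air,0.001205,O,0.235000
pmma,1.190,H,0.080538
pmma,1.190,C,0.599848
pmma,1.190,O,0.319614
acrylic,1.180,H,0.080538
acrylic,1.180,C,0.599848
acrylic,1.180,O,0.319614
polystyrene,1.050,H,0.077418
polystyrene,1.050,C,0.922582
ldpe,0.920,H,0.143711
ldpe,0.920,C,0.856289
pmp,0.830,H,0.143711
pmp,0.830,C,0.856289
delrin,1.410,H,0.067135
delrin,1.410,C,0.400017
delrin,1.410,O,0.532848
teflon,2.160,C,0.240183
teflon,2.160,F,0.759817
aluminum,2.699,Al,1.000000
bone20,1.140,H,0.064800
bone20,1.140,C,0.479800
bone20,1.140,O,0.338600
bone20,1.140,P,0.037000
bone20,1.140,Ca,0.079800
bone50,1.400,H,0.041300
bone50,1.400,C,0.299900
bone50,1.400,O,0.366800
bone50,1.400,P,0.092500
bone50,1.400,Ca,0.199500
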