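protocol,framerate_s,cumulative_mAs,kvp,estimate_mGy,measured_mGy,printed_diff_pct
1,3,338,80,5.8,5.7,2.5
2,7,788,80,13.3,13.3,0.2
3,11,1238,80,20.8,20.9,0.6
5,15,405,80,7.0,7.0,0.2
6,15,810,80,13.7,13.6,0.6
7,15,1170,80,19.7,19.6,0.2
8,15,1688,80,28.3,28.2,0.3
1,3,338,140,29.0,27.4,5.8
2,7,788,140,64.5,63.7,1.2
3,11,1238,140,99.9,100.2,0.2
5,15,405,140,34.3,34.9,1.5
6,15,810,140,66.3,66.2,0.1
7,15,1170,140,94.6,94.8,0.2
8,15,1688,140,135.4,135.2,0.1
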