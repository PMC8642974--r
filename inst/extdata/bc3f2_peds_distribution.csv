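env,peds_eq_0,c0_10,c10_20,c20_30,c30_40,c40_50,c50_60,c60_70,c70_80,c80_90,c90_100,total,mean_reported
14WJ,4048,1,0,0,2,3,23,35,33,72,103,4320,5.04
14EEDS,4683,0,0,3,8,14,25,39,74,88,88,5022,5.19
14JH,7466,3,8,23,26,43,65,60,83,93,120,7990,4.59
15JH,6336,384,0,0,0,0,0,0,0,0,0,6720,0.29
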