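"gender","age_band","segment","param","mu","sigma"
0,"all","L1L2","delta_si",153,10
0,"all","L1L2","DHI",0.35,0.05
0,"all","L1L2","HDR",0.166666666666667,0.02
0,"all","L1L2","DH",14,1.5
1,"all","L1L2","delta_si",153,10
1,"all","L1L2","DHI",0.35,0.05
1,"all","L1L2","HDR",0.166666666666667,0.02
1,"all","L1L2","DH",14,1.5
0,"all","L2L3","delta_si",153,10
0,"all","L2L3","DHI",0.35,0.05
0,"all","L2L3","HDR",0.166666666666667,0.02
0,"all","L2L3","DH",14,1.5
1,"all","L2L3","delta_si",153,10
1,"all","L2L3","DHI",0.35,0.05
1,"all","L2L3","HDR",0.166666666666667,0.02
1,"all","L2L3","DH",14,1.5
0,"all","L3L4","delta_si",153,10
0,"all","L3L4","DHI",0.35,0.05
0,"all","L3L4","HDR",0.166666666666667,0.02
0,"all","L3L4","DH",14,1.5
1,"all","L3L4","delta_si",153,10
1,"all","L3L4","DHI",0.35,0.05
1,"all","L3L4","HDR",0.166666666666667,0.02
1,"all","L3L4","DH",14,1.5
0,"all","L4L5","delta_si",153,10
0,"all","L4L5","DHI",0.35,0.05
0,"all","L4L5","HDR",0.166666666666667,0.02
0,"all","L4L5","DH",14,1.5
1,"all","L4L5","delta_si",153,10
1,"all","L4L5","DHI",0.35,0.05
1,"all","L4L5","HDR",0.166666666666667,0.02
1,"all","L4L5","DH",14,1.5
0,"all","L5S1","delta_si",153,10
0,"all","L5S1","DHI",0.35,0.05
0,"all","L5S1","HDR",0.166666666666667,0.02
0,"all","L5S1","DH",14,1.5
1,"all","L5S1","delta_si",153,10
1,"all","L5S1","DHI",0.35,0.05
1,"all","L5S1","HDR",0.166666666666667,0.02
1,"all","L5S1","DH",14,1.5
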