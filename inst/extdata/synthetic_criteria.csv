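"grade","mu","sigma"
1,150,10
2,118.2375,10
3,86.475,10
4,54.7125,10
5,22.95,10
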