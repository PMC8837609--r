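{"background":0,"VB_L1":1,"VB_L2":2,"VB_L3":3,"VB_L4":4,"VB_L5":5,"DISC_L1L2":6,"DISC_L2L3":7,"DISC_L3L4":8,"DISC_L4L5":9,"DISC_L5S1":10,"SACRUM":11,"PRESACRAL_FAT":12,"CSF":13}
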