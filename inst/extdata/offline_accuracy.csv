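patient,accuracy,num_ps
1,0.941,30
2,0.986,60
3,0.959,15
4,0.913,30
5,0.947,40
6,0.958,30
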