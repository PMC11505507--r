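subject,fog_pct,other_pct,n_fog_episodes,n_samples
1,4.7,95.3,NA,54030
2,1.5,98.5,8,97227
3,1.9,98.1,10,99175
4,8.6,91.4,16,58620
5,7.6,92.4,86,92987
6,3.0,97.0,6,25313
7,6.2,93.8,7,9480
8,4.8,95.2,4,12309
9,15.4,84.6,13,14055
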