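power_mW,t_s,dT_K,se_K
69.5,60,2.69,0.37
178,120,4.70,0.68
286.5,180,6.70,0.94
395,240,8.47,0.81
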