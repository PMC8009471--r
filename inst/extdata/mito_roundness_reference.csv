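condition,median_rho,median_se,frac_rho_le_0.3,frac_rho_0.3_0.7,frac_rho_0.7_1
control,0.57,0.01,0.101,0.631,0.268
LPDNP,0.57,0.01,0.118,0.595,0.287
TBH,0.70,0.01,0.033,0.473,0.494
LPDNP_TBH,0.62,0.01,0.089,0.529,0.381
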