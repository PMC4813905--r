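cohort_id,probe_material,probe_w_um,probe_t_um,probe_L_um,coat_t_um,coat_w_um,coat_L_um,tissue,n_total,n_pass,success_rate_pct
1,su8,40,10,3500,NA,NA,NA,rat,11,6,54.5
2,su8,40,10,3500,100,100,4000,rat,12,12,100.0
3,parylene_c,40,2.5,3500,NA,NA,NA,rat,8,0,0.0
4,parylene_c,40,2.5,3500,50,100,4000,rat,8,5,62.5
5,parylene_c,40,2.5,3500,75,100,4000,rat,8,7,87.5
6,parylene_c,40,2.5,3500,100,100,4000,rat,12,12,100.0
7,shank,NA,NA,NA,100,100,4000,rat,8,8,100.0
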