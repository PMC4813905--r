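cohort_id,probe_material,probe_w_um,probe_t_um,probe_L_um,coat_t_um,coat_w_um,coat_L_um,tissue,n_total,n_pass,success_rate_pct
1,su8,320,5,3500,NA,NA,NA,chick,8,8,100.0
2,su8,320,20,3500,NA,NA,NA,chick,8,8,100.0
3,su8,320,20,3500,50,50,4000,chick,8,8,100.0
4,su8,320,20,3500,75,100,4000,chick,8,8,100.0
5,su8,320,20,3500,100,100,4000,chick,8,8,100.0
6,parylene_c,20,5,3500,NA,NA,NA,chick,8,0,0.0
7,parylene_c,100,5,3500,NA,NA,NA,chick,8,0,0.0
8,parylene_c,320,5,3500,NA,NA,NA,chick,8,0,0.0
9,parylene_c,320,20,3500,NA,NA,NA,chick,8,0,0.0
10,parylene_c,20,5,3500,50,50,4000,chick,8,4,50.0
11,parylene_c,20,5,3500,50,100,4000,chick,8,7,87.5
12,parylene_c,20,5,3500,75,100,4000,chick,8,8,100.0
13,parylene_c,20,5,3500,100,100,4000,chick,8,8,100.0
14,parylene_c,20,5,3500,250,100,4000,chick,8,8,100.0
15,parylene_c,20,5,3500,350,100,4000,chick,8,8,100.0
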