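diet,corn,soybean_meal,corn_starch,pea_starch,tapioca_starch,soybean_oil,casein,dicalcium_phosphate,l_lysine_hcl,dl_methionine,l_threonine,l_tryptophan,l_valine,salt,limestone,premix,dm,ash,ee,ndf,adf,cp,ge
T1,72.90,23.20,0,0,0,0,0,0.85,0.50,0.09,0.10,0.04,0.01,0.21,1.10,1.00,85.99,4.36,2.90,11.14,4.03,16.31,17.53
T2,51.44,16.37,27.00,0,0,0,0,1.00,0.96,0.23,0.25,0.08,0.21,0.26,1.20,1.00,85.91,4.18,2.05,7.83,2.70,12.35,17.09
T3,51.44,16.37,0,27.00,0,0,0,1.00,0.96,0.23,0.25,0.08,0.21,0.26,1.20,1.00,86.23,4.23,2.01,7.40,2.29,12.08,17.15
T4,51.44,16.37,0,0,27.00,0,0,1.00,0.96,0.23,0.25,0.08,0.21,0.26,1.20,1.00,85.83,4.13,2.03,7.28,2.47,12.19,17.22
T5,68.75,21.88,0,0,0,5.00,0,0.90,0.73,0.12,0.13,0.05,0.05,0.29,1.10,1.00,87.74,4.41,6.92,9.81,3.27,16.03,18.33
T6,64.39,20.49,0,0,0,0,11.80,0.80,0,0.05,0.01,0.04,0.01,0.31,1.10,1.00,85.09,4.23,2.50,9.67,3.07,23.58,17.84
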