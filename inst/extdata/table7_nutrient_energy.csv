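item,basal,corn_starch,pea_starch,tapioca_starch,soybean_oil,casein,sem
dj,0.87,0.99,0.99,1.00,0.96,0.95,0.01
mj,0.97,0.99,0.95,0.95,0.99,0.88,0.01
pj,0.19,0.05,0.05,0.05,0.12,0.51,0.03
kj,0.81,0.88,0.80,0.86,0.95,0.68,0.02
ge,18.36,16.13,16.30,17.02,37.97,20.20,1.43
de,16.02,16.03,16.06,17.07,36.49,19.18,1.39
me,15.52,15.77,15.37,16.34,36.16,16.89,1.42
ne,14.50,15.06,14.37,15.22,34.03,16.22,1.80
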