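item,unit,T1,T2,T3,T4,T5,T6,sem
mei,kJ/kg BW^0.6/d,2066.73,2036.18,2018.06,2039.59,2027.80,2013.16,30.53
thp,kJ/kg BW^0.6/d,1176.64,1150.69,1173.54,1168.28,1093.23,1112.11,39.03
fhp,kJ/kg BW^0.6/d,853.09,854.36,827.46,823.37,834.21,847.62,48.16
total_re,kJ/kg BW^0.6/d,890.09,885.49,844.52,871.31,934.57,901.05,53.13
pd,kJ/kg BW^0.6/d,386.42,279.48,278.27,281.00,351.86,518.03,16.57
ld,kJ/kg BW^0.6/d,503.66,606.01,566.25,590.30,582.71,383.02,17.44
rq,-,1.03,1.03,1.03,1.04,1.01,1.01,NA
fasted_rq,-,0.83,0.81,0.81,0.81,0.82,0.83,NA
de,MJ/kg DM,17.79,18.15,18.09,18.38,18.57,18.66,0.07
me,MJ/kg DM,17.23,17.68,17.45,17.72,18.07,17.69,0.07
ne,MJ/kg DM,14.50,15.13,14.49,14.78,15.76,15.43,0.13
me_de,%,97.00,97.20,96.60,96.40,97.00,94.80,0.74
ne_me,%,84.20,85.60,83.00,83.40,87.00,87.40,2.31
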