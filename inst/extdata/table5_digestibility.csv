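item,unit,T1,T2,T3,T4,T5,T6,sem
bw,kg,30.66,30.63,29.69,29.62,30.64,30.72,0.28
dm_intake,g/d,935,897,884,878,874,889,21.28
attd_ge,%,87.28,91.23,90.97,91.59,88.89,88.98,0.38
attd_om,%,87.19,91.51,91.27,91.82,88.91,88.96,0.41
attd_cp,%,86.90,88.68,87.74,89.26,86.26,90.01,0.47
attd_ee,%,54.75,54.60,53.70,50.39,79.47,52.60,2.11
attd_ndf,%,54.87,56.85,55.60,54.62,56.15,50.91,1.11
attd_adf,%,48.13,47.90,43.94,51.83,45.99,39.22,1.45
n_intake,g/d,28.38,20.63,19.83,19.96,25.57,39.39,1.30
fecal_n,g/d,3.71,2.32,2.43,2.13,3.52,3.94,0.16
urinary_n,g/d,4.44,3.69,3.12,3.43,3.68,8.34,0.38
n_retention,g/d,20.22,14.62,14.27,14.40,18.37,27.11,0.89
net_protein_availability,fraction,0.71,0.71,0.72,0.72,0.72,0.69,0.02
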