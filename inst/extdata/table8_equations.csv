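response,intercept,ge,cp,ee,starch,ndf,adf,ash,r2,rmse,aic,bic,validation_r2
pd,-23.37,NA,23.50,NA,NA,NA,NA,NA,0.87,173.36,373.09,376.08,0.78
pd,37.56,NA,28.98,NA,NA,NA,-24.51,NA,0.96,105.45,346.89,350.48,0.77
pd,48.64,NA,29.64,NA,NA,NA,-23.77,-7.77,0.96,106.99,349.54,353.48,0.77
pd,364.36,-18.44,29.10,-3.79,NA,NA,-21.37,NA,0.96,105.15,350.66,354.65,0.80
pd,509.27,-17.47,26.61,-5.41,-2.01,NA,-24.37,NA,0.96,106.18,353.56,357.28,0.79
pd,640.63,-17.12,24.56,-6.88,-3.36,-2.49,-21.91,NA,0.96,108.06,357.21,360.29,0.80
pd,643.11,-18.60,24.54,-7.02,-3.13,-2.21,-22.21,3.45,0.96,110.66,361.60,363.59,0.80
ld,3106.14,-141.09,NA,NA,NA,NA,NA,NA,0.88,359.68,413.96,416.95,0.88
ld,1.25,NA,NA,35.15,11.46,NA,NA,NA,0.96,199.62,382.62,386.21,0.97
ld,-200.77,NA,NA,37.34,13.10,6.37,NA,NA,0.97,193.09,382.61,386.54,0.97
ld,-1276.12,NA,16.77,49.36,24.81,15.65,NA,NA,0.97,183.93,381.97,385.96,0.97
ld,-1503.50,NA,21.58,51.98,26.30,26.81,-23.87,NA,0.98,172.85,380.85,384.57,0.97
ld,-1424.08,-5.51,21.91,51.11,26.46,26.91,-22.82,NA,0.98,176.67,384.74,387.82,0.97
ld,-1413.85,-11.61,21.86,50.55,27.41,28.06,-24.06,14.23,0.98,180.37,388.96,390.95,0.97
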