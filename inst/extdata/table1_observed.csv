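study_ref,phenotype,route,dose_mg,regimen,inf_min,training,obs_auc,auc_lo,auc_hi,pred_auc,obs_cmax,cmax_lo,cmax_hi,pred_cmax
kinzig2005,FA,iv,200,sd,20,1,8.0,5.36,11.84,10.60,5.2,2.60,10.30,7.83
kinzig2005,FA,po,100,sd,NA,1,3.1,2.08,4.59,3.42,1.2,0.60,2.38,1.64
kinzig2005,FA,po,300,sd,NA,1,12.3,8.24,18.20,11.89,5.4,2.70,10.69,5.39
kinzig2005,SA,iv,200,sd,20,1,20.4,10.20,40.19,21.30,6.8,1.90,24.21,8.42
kinzig2005,SA,po,100,sd,NA,1,9.1,4.55,17.93,8.96,2.1,0.59,7.48,2.20
kinzig2005,SA,po,300,sd,NA,1,32.1,16.05,63.24,27.86,7.8,2.18,27.77,6.74
kinzig2005,IA,iv,200,sd,20,0,10.6,9.01,12.40,13.25,6.0,3.66,9.78,7.75
kinzig2005,IA,po,100,sd,NA,0,4.8,4.08,5.62,5.09,1.3,0.79,2.12,1.85
kinzig2005,IA,po,300,sd,NA,0,17.1,14.54,20.01,16.50,6.15,3.75,10.02,5.85
kubota2013,IA,po,300,sd,NA,0,14.24,12.10,16.66,15.82,6.77,4.13,11.04,5.45
bing2011,IA,po,300,sd,NA,0,16.34,13.89,19.12,15.83,5.72,3.49,9.32,5.48
boxenbaum1976,FA,iv,670,sd,5.2,0,35.65,23.89,52.76,38.42,37.16,18.58,73.58,56.81
kubota2013,FA,po,300,sd,NA,0,9.54,6.39,14.12,11.65,5.72,2.86,11.33,4.99
kubota2013,FA,po,600,sd,NA,0,24.99,16.74,36.99,26.70,13.92,6.96,27.56,11.72
kubota2013,FA,po,900,sd,NA,0,48.19,32.29,71.23,45.24,21.49,10.75,42.55,17.93
bing2011,FA,po,300,sd,NA,0,10.35,6.93,15.32,11.66,4.93,2.47,9.76,5.06
yoo2020,FA,po,300,sd,NA,0,6.29,4.21,9.31,9.82,3.74,1.87,7.41,4.28
yoo2020,FA,po,300,md,NA,0,6.66,4.46,9.86,10.01,3.58,1.79,7.09,4.43
boxenbaum1976,SA,iv,670,sd,5.4,0,55.46,27.73,109.26,59.61,35.08,9.82,124.88,55.65
bing2011,SA,po,300,sd,NA,0,42.24,21.12,83.21,32.68,8.28,2.32,29.48,6.57
yoo2020,SA,po,200,sd,NA,0,15.10,7.55,29.75,18.05,3.05,0.85,10.86,4.88
yoo2020,SA,po,200,md,NA,0,18.90,9.45,37.23,18.31,4.06,1.14,14.45,4.92
yoo2020,SA,po,300,sd,NA,0,27.0,13.50,53.19,27.52,5.0,1.40,17.80,7.38
yoo2020,SA,po,300,md,NA,0,28.0,14.00,55.16,27.92,6.57,1.84,23.39,7.44
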