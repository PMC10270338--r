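dataset,n,y1,condition,kind,param,sum_abs_diffs,mean,max,min,normalised
keystrokes,56545,3.63,Original Matrix Profile,original,NA,0,1.87,3.63,0.33,0
keystrokes,56545,3.63,Duplicated Anomaly x 2,duplicated_anomaly,2,9306,1.88,3.71,0.37,0.045
keystrokes,56545,3.63,Duplicated Anomaly x 3,duplicated_anomaly,3,10669,1.88,3.58,0.36,0.051
keystrokes,56545,3.63,Duplicated Anomaly x 4,duplicated_anomaly,4,11856,1.86,3.61,0.34,0.057
keystrokes,56545,3.63,Duplicated Anomaly x 5,duplicated_anomaly,5,12820,1.86,3.58,0.39,0.062
keystrokes,56545,3.63,Duplicated Anomaly x 6,duplicated_anomaly,6,14053,1.86,3.56,0.39,0.068
keystrokes,56545,3.63,Irrelevant Features - 1%,irrelevant_features,0.01,9683,1.80,3.64,0.30,0.047
keystrokes,56545,3.63,Irrelevant Features - 5%,irrelevant_features,0.05,15333,1.54,3.76,0.33,0.074
keystrokes,56545,3.63,Irrelevant Features - 10%,irrelevant_features,0.10,19528,1.39,3.85,0.38,0.095
keystrokes,56545,3.63,Irrelevant Features - 25%,irrelevant_features,0.25,25787,1.42,3.86,0.42,0.125
keystrokes,56545,3.63,Irrelevant Features - 50%,irrelevant_features,0.50,27368,1.66,3.2,0.47,0.133
calf_amag,60480,8.28,Original Matrix Profile,original,NA,0,5.10,8.28,0.63,0
calf_amag,60480,8.28,Duplicated Anomaly x 2,duplicated_anomaly,2,23585,5.41,8.05,0.06,0.047
calf_amag,60480,8.28,Duplicated Anomaly x 3,duplicated_anomaly,3,31467,5.71,8.15,0.09,0.062
calf_amag,60480,8.28,Duplicated Anomaly x 4,duplicated_anomaly,4,38424,5.93,8.21,2.32,0.076
calf_amag,60480,8.28,Duplicated Anomaly x 5,duplicated_anomaly,5,50321,6.04,8.21,2.79,0.100
calf_amag,60480,8.28,Duplicated Anomaly x 6,duplicated_anomaly,6,51830,6.19,8.27,2.45,0.103
calf_amag,60480,8.28,Irrelevant Features - 1%,irrelevant_features,0.01,19811,5.09,8.09,0.05,0.039
calf_amag,60480,8.28,Irrelevant Features - 5%,irrelevant_features,0.05,32825,5.46,7.90,0.06,0.065
calf_amag,60480,8.28,Irrelevant Features - 10%,irrelevant_features,0.10,47781,5.92,7.85,2.10,0.095
calf_amag,60480,8.28,Irrelevant Features - 25%,irrelevant_features,0.25,97028,6.68,7.96,3.88,0.193
calf_amag,60480,8.28,Irrelevant Features - 50%,irrelevant_features,0.50,117820,7.01,8.13,5.12,0.235
traffic,3600,2.25,Original Matrix Profile,original,NA,0,0.34,2.25,0.13,0
traffic,3600,2.25,Duplicated Anomaly x 2,duplicated_anomaly,2,1739,0.91,4.09,0.13,0.214
traffic,3600,2.25,Duplicated Anomaly x 3,duplicated_anomaly,3,2724,1.39,4.23,0.20,0.336
traffic,3600,2.25,Duplicated Anomaly x 4,duplicated_anomaly,4,2992,1.70,4.49,0.20,0.369
traffic,3600,2.25,Duplicated Anomaly x 5,duplicated_anomaly,5,3864,1.99,4.52,0.26,0.477
traffic,3600,2.25,Duplicated Anomaly x 6,duplicated_anomaly,6,4701,2.17,4.66,0.48,0.580
traffic,3600,2.25,Irrelevant Features - 1%,irrelevant_features,0.01,764,0.54,3.29,0.13,0.094
traffic,3600,2.25,Irrelevant Features - 5%,irrelevant_features,0.05,2109,1.08,3.96,0.16,0.260
traffic,3600,2.25,Irrelevant Features - 10%,irrelevant_features,0.10,2705,1.59,3.84,0.20,0.333
traffic,3600,2.25,Irrelevant Features - 25%,irrelevant_features,0.25,4567,2.47,4.46,0.61,0.563
traffic,3600,2.25,Irrelevant Features - 50%,irrelevant_features,0.50,11617,3.17,4.46,1.34,1.434
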