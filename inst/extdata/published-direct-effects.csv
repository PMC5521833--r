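model,exposure,outcome,from,to,estimate,p_value
1a,dgla,sbp_z,snp,dgla,0.353,0.0001
1a,dgla,sbp_z,dgla,bmi_z,0.164,0.001
1a,dgla,sbp_z,snp,bmi_z,-0.134,0.002
1a,dgla,sbp_z,bmi_z,sbp_z,0.288,0.0001
1a,dgla,sbp_z,dgla,sbp_z,-0.002,0.968
1a,dgla,sbp_z,snp,sbp_z,0.043,0.352
2a,ara,sbp_z,snp,ara,-0.237,0.0001
2a,ara,sbp_z,ara,bmi_z,0.076,0.243
2a,ara,sbp_z,snp,bmi_z,-0.058,0.167
2a,ara,sbp_z,bmi_z,sbp_z,0.282,0.0001
2a,ara,sbp_z,ara,sbp_z,0.149,0.040
2a,ara,sbp_z,snp,sbp_z,0.077,0.085
3a,epa,sbp_z,snp,epa,-0.092,0.016
3a,epa,sbp_z,epa,bmi_z,0.147,0.001
3a,epa,sbp_z,snp,bmi_z,-0.061,0.122
3a,epa,sbp_z,bmi_z,sbp_z,0.284,0.0001
3a,epa,sbp_z,epa,sbp_z,0.027,0.576
3a,epa,sbp_z,snp,sbp_z,0.044,0.288
4a,d5d,sbp_z,snp,d5d,-0.527,0.0001
4a,d5d,sbp_z,d5d,bmi_z,-0.097,0.040
4a,d5d,sbp_z,snp,bmi_z,-0.125,0.007
4a,d5d,sbp_z,bmi_z,sbp_z,0.291,0.0001
4a,d5d,sbp_z,d5d,sbp_z,0.035,0.482
4a,d5d,sbp_z,snp,sbp_z,0.061,0.217
1b,dgla,dbp_z,snp,dgla,0.353,0.0001
1b,dgla,dbp_z,dgla,bmi_z,0.164,0.001
1b,dgla,dbp_z,snp,bmi_z,-0.134,0.002
1b,dgla,dbp_z,bmi_z,dbp_z,0.139,0.002
1b,dgla,dbp_z,dgla,dbp_z,-0.003,0.954
1b,dgla,dbp_z,snp,dbp_z,-0.006,0.904
2b,ara,dbp_z,snp,ara,-0.237,0.0001
2b,ara,dbp_z,ara,bmi_z,0.076,0.243
2b,ara,dbp_z,snp,bmi_z,-0.058,0.167
2b,ara,dbp_z,bmi_z,dbp_z,0.134,0.003
2b,ara,dbp_z,ara,dbp_z,0.103,0.158
2b,ara,dbp_z,snp,dbp_z,0.017,0.698
3b,epa,dbp_z,snp,epa,-0.092,0.016
3b,epa,dbp_z,epa,bmi_z,0.147,0.001
3b,epa,dbp_z,snp,bmi_z,-0.061,0.122
3b,epa,dbp_z,bmi_z,dbp_z,0.134,0.003
3b,epa,dbp_z,epa,dbp_z,0.031,0.512
3b,epa,dbp_z,snp,dbp_z,-0.004,0.922
4b,d5d,dbp_z,snp,d5d,-0.527,0.0001
4b,d5d,dbp_z,d5d,bmi_z,-0.097,0.040
4b,d5d,dbp_z,snp,bmi_z,-0.125,0.007
4b,d5d,dbp_z,bmi_z,dbp_z,0.141,0.002
4b,d5d,dbp_z,d5d,dbp_z,0.036,0.481
4b,d5d,dbp_z,snp,dbp_z,0.012,0.804
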