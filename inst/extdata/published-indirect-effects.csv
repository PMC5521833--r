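model,source,target,estimate,p_value
1a,snp,bmi_z,0.058,0.002
1a,snp,sbp_z,-0.023,0.328
1a,dgla,sbp_z,0.047,0.004
2a,snp,bmi_z,-0.018,0.247
2a,snp,sbp_z,-0.057,0.007
2a,ara,sbp_z,0.021,0.251
3a,snp,bmi_z,-0.014,0.052
3a,snp,sbp_z,-0.024,0.060
3a,epa,sbp_z,0.042,0.004
4a,snp,bmi_z,0.051,0.042
4a,snp,sbp_z,-0.040,0.170
4a,d5d,sbp_z,-0.028,0.051
1b,snp,bmi_z,0.058,0.002
1b,snp,dbp_z,-0.012,0.587
1b,dgla,dbp_z,0.023,0.028
2b,snp,bmi_z,-0.018,0.247
2b,snp,dbp_z,-0.035,0.061
2b,ara,dbp_z,0.010,0.278
3b,snp,bmi_z,-0.014,0.052
3b,snp,dbp_z,-0.013,0.091
3b,epa,dbp_z,0.020,0.029
4b,snp,bmi_z,0.051,0.042
4b,snp,dbp_z,-0.029,0.291
4b,d5d,dbp_z,-0.014,0.087
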