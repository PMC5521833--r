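stratum,n,outcome,effect_type,from,to,estimate,p_value
thin_normal,316,sbp_z,direct,epa,sbp_z,-0.042,0.568
thin_normal,316,sbp_z,direct,epa,bmi_z,-0.206,0.0001
thin_normal,316,sbp_z,indirect,epa,sbp_z,-0.029,0.060
overweight_obese,204,sbp_z,direct,epa,sbp_z,0.155,0.039
overweight_obese,204,sbp_z,direct,epa,bmi_z,0.535,0.0001
overweight_obese,204,sbp_z,indirect,epa,sbp_z,0.075,0.040
thin_normal,316,dbp_z,direct,epa,dbp_z,-0.023,0.756
thin_normal,316,dbp_z,direct,epa,bmi_z,-0.206,0.0001
thin_normal,316,dbp_z,indirect,epa,dbp_z,-0.002,0.860
overweight_obese,204,dbp_z,direct,epa,dbp_z,0.143,0.058
overweight_obese,204,dbp_z,direct,epa,bmi_z,0.535,0.0001
overweight_obese,204,dbp_z,indirect,epa,dbp_z,0.006,0.860
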