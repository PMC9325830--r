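product_id,active_id,formulation_code,test_system,preparation,applied_dose_ug_cm2,concentration_g_L,observation_time_h,rf_pct,skin_pct,ts12_pct
FMC_P2_CS,FMC_A2,CS,in_vitro_human,dilution,62.37,6.237,24,5.2,,
FMC_P2_CS,FMC_A2,CS,in_vitro_human,dilution,31.43,3.143,24,8.93,,
FMC_P2_CS,FMC_A2,CS,in_vitro_human,dilution,22.71,2.271,24,12.54,,
FMC_P2_CS,FMC_A2,CS,in_vitro_human,dilution,16.45,1.645,24,13.96,,
BAY_P6_WG,BAY_A6,WG,in_vitro_human,dilution,29.7,2.97,24,1.32,,
BAY_P6_WG,BAY_A6,WG,in_vitro_human,dilution,14.8,1.48,24,1.8,,
BAY_P6_WG,BAY_A6,WG,in_vitro_human,dilution,8.8,0.88,24,1.3,,
SYN_P10_SC,SYN_A10,SC,in_vitro_human,dilution,49.8,4.98,24,2.54,,
SYN_P10_SC,SYN_A10,SC,in_vitro_human,dilution,26.2,2.62,24,3.0,,
SYN_P10_SC,SYN_A10,SC,in_vitro_human,dilution,16.5,1.65,24,1.29,,
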