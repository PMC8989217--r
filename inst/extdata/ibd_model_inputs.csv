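name,base,low,high,family,units
p_uc,0.568,0.483,0.654,beta,proportion
h_uc,0.186,0.158,0.213,beta,per patient-year
s_uc,0.051,0.043,0.059,beta,per hospitalization
m_uc,0.003,0.003,0.003,beta,per hospitalization
h_cd,0.225,0.191,0.258,beta,per patient-year
s_cd,0.331,0.282,0.381,beta,per hospitalization
m_cd,0.018,0.015,0.021,beta,per hospitalization
p_avoid,0.261,0.222,0.3,beta,proportion
rr_avoid,1.156,1.05,1.329,lognormal,relative risk
p_comply,0.59,0.502,0.679,beta,proportion
rr_tm,0.364,0.31,0.419,lognormal,relative risk
cost_visit_uc,858,729,987,gamma,USD/patient-year
cost_meds_uc,3060,2607,3528,gamma,USD/patient-year
cost_imaging_uc,74,63,85,gamma,USD/patient-year
cost_endoscopy_uc,3647,3100,4194,gamma,USD/patient-year
cost_hosp_uc,7290,6197,8384,gamma,USD/patient-year
cost_surgery_uc,5765,4900,6630,gamma,USD/patient-year
cost_death_uc,26990,22942,31039,gamma,USD/patient-year
cost_visit_cd,1129,960,1298,gamma,USD/patient-year
cost_meds_cd,2894,2460,3328,gamma,USD/patient-year
cost_imaging_cd,485,412,558,gamma,USD/patient-year
cost_endoscopy_cd,3328,2829,3827,gamma,USD/patient-year
cost_hosp_cd,9389,7981,10797,gamma,USD/patient-year
cost_surgery_cd,5534,4704,6364,gamma,USD/patient-year
cost_death_cd,44596,37907,51285,gamma,USD/patient-year
visit_reduction,0.261,0.222,0.3,lognormal,proportion
tm_maintenance,50,43,58,gamma,USD/year
tm_encounters,4.76,4.046,5.474,normal,per patient-year
tm_encounter_hours,0.25,0.213,0.288,normal,hours
tm_wage,101,86,116,gamma,USD/hour
rr_imaging_tm,1.565,1.331,1.8,lognormal,relative risk
u_out,0.83,0.789,0.872,beta,utility
u_hosp,0.55,0.523,0.578,beta,utility
u_surg,0.4,0.38,0.42,beta,utility
wtp,46450,46450,46450,point,USD/QALY
horizon,1,1,1,point,years
usd_to_hkd,7.8,7.8,7.8,point,HKD per USD
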