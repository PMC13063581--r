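reason,k_all,n_all,k_both,n_both,k1,n1,k2,n2
risk_too_low,110,431,13,63,75,301,22,67
no_prescriber,88,431,19,63,55,301,14,67
doctor_visit_effort,148,431,24,63,109,301,15,67
discuss_sex_life,116,431,19,63,83,301,14,67
negative_reactions,33,431,7,63,25,301,1,67
side_effects,235,431,27,63,171,301,37,67
daily_pill,89,431,15,63,51,301,23,67
medical_reasons,4,431,0,63,4,301,0,67
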