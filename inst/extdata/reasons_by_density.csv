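reason,k_all,n_all,k1,n1,k2,n2
risk_too_low,110,431,80,332,29,81
no_prescriber,88,431,70,332,12,81
doctor_visit_effort,148,431,122,332,23,81
discuss_sex_life,116,431,98,332,13,81
negative_reactions,33,431,27,332,3,81
side_effects,235,431,172,332,55,81
daily_pill,89,431,65,332,21,81
medical_reasons,4,431,3,332,1,81
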