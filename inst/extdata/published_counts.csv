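quantity,numerator,denominator,scale,digits
shock_share_pct,649082,4426342,percent,1
sepsis_prevalence_pct,4426342,82170094,percent,1
inhospital_mortality_pct,833815,3696098,percent,1
deaths_per_1000_overall,833815,82170094,per1000,2
deaths_per_1000_shock,212591,82170094,per1000,2
deaths_per_1000_nonshock,621224,82170094,per1000,2
icu_admission_pct,1053792,4426342,percent,2
icu_admission_shock_pct,329005,649082,percent,1
female_shock_pct,246406,649082,percent,1
hydrocortisone_shock_pct,85563,649082,percent,1
community_onset_pct,2669220,4426342,percent,1
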