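genotype,age_weeks,stage,endplate_scale,ribbon_width,n_branches,dim_fraction,dim_source,floccular_fraction,floccular_source,p_extrajunctional,bright_intensity,dim_intensity,background_level,noise_sd
WT,4,developing,25,3,4,0.25,assumed,0.00,assumed,0.10,185,80,20,5
WT,8,developing,30,3,4,0.32,assumed,0.00,assumed,0.10,185,80,20,5
WT,12,adult,35,3,4,0.40,printed,0.00,assumed,0.10,185,80,20,5
WT,16,adult,38,3,4,0.40,printed,0.00,assumed,0.10,185,80,20,5
WT,20,symptomatic_age_match,40,3,4,0.40,printed,0.00,assumed,0.10,185,80,20,5
SOD1,4,developing,25,3,4,0.25,assumed,0.00,assumed,0.10,185,80,20,5
SOD1,8,developing,30,3,4,0.32,assumed,0.00,assumed,0.10,185,80,20,5
SOD1,12,adult,35,3,4,0.40,printed,0.10,assumed,0.10,185,80,20,5
SOD1,16,adult,38,3,4,0.50,assumed,0.30,assumed,0.10,185,80,20,5
SOD1,20,early_symptomatic,40,3,4,0.60,printed,0.55,assumed,0.10,185,80,20,5
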