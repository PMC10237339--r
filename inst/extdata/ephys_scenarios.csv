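genotype,age_weeks,stage,mepp_mean,mepp_source,mepp_cv,mepp_rate,rate_source,epp_mean,epp_source,qc_reduction_vs_wt,rise_time,decay_tau,rmp_mean,rmp_drift_sd,noise_sd,release_fraction,replenish_rate
WT,2,developing,1.48,printed,0.30,0.5,assumed,12.0,assumed,NA,0.8,4,-70,1.5,0.15,0.2,0.25
WT,4,developing,1.25,assumed,0.30,0.8,assumed,20.0,assumed,NA,0.8,4,-70,1.5,0.15,0.2,0.30
WT,8,developing,1.06,printed,0.30,1.1,assumed,27.0,assumed,NA,0.8,4,-70,1.5,0.15,0.2,0.35
WT,12,adult,1.12,assumed,0.30,1.3,assumed,31.0,assumed,NA,0.8,4,-70,1.5,0.15,0.2,0.35
WT,16,adult,1.15,assumed,0.30,1.3,assumed,33.0,assumed,NA,0.8,4,-70,1.5,0.15,0.2,0.35
WT,20,symptomatic_age_match,1.19,printed,0.30,1.3,assumed,34.3,printed,NA,0.8,4,-70,1.5,0.15,0.2,0.28
SOD1,2,developing,1.55,assumed,0.30,0.5,assumed,12.5,assumed,NA,0.8,4,-70,1.5,0.15,0.2,0.25
SOD1,4,developing,1.35,assumed,0.30,0.8,assumed,21.0,assumed,NA,0.8,4,-70,1.5,0.15,0.2,0.30
SOD1,8,developing,1.30,printed,0.30,1.1,assumed,28.0,assumed,NA,0.8,4,-70,1.5,0.15,0.2,0.35
SOD1,12,adult,1.12,assumed,0.30,1.3,assumed,27.0,assumed,NA,0.65,4,-70,1.5,0.15,0.2,0.20
SOD1,16,adult,1.15,assumed,0.30,0.7319,derived_printed_ratio,NA,derived_printed_ratio,0.277,0.8,4,-70,1.5,0.15,0.2,0.16
SOD1,20,early_symptomatic,0.94,printed,0.30,1.3,assumed,30.6,printed,NA,0.8,4,-70,1.5,0.15,0.2,0.12
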