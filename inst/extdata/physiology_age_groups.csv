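age_group,body_weight,bw_gsd,daily_urine_volume,daily_creatinine,urine_creatinine
<6,18,1.25,0.55,0.35,0.60
6-11,31,1.30,0.75,0.65,0.85
12-19,62,1.25,1.20,1.30,1.25
20-65,80,1.22,1.55,1.50,1.20
>65,75,1.20,1.45,1.20,1.00
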