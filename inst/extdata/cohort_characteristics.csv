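characteristic,n,mean,range_min,range_max,ci_lo,ci_hi
n_male,221,NA,NA,NA,NA,NA
n_female,223,NA,NA,NA,NA,NA
gestational_age_wk,444,38.9,33,42,38.7,39.0
parity,444,1.3,0,9,1.1,1.4
birthweight_kg,444,3.46,1.93,4.89,3.41,3.50
weight_gain_kg_per_mo,229,0.73,0.34,1.22,0.71,0.75
bmi_9y,240,20.7,13.9,33.8,20.1,21.3
bmi_z_9y,240,1.11,-1.57,2.70,0.98,1.24
maternal_age_yr,444,25.6,18,43,25.1,26.1
maternal_bmi,444,27.0,17.7,57.3,26.5,27.5
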