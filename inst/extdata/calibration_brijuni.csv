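specimen_id,species,depth_top_cm,depth_bottom_cm,dl_asp,dl_glu,dl_ser,dl_ala,cal_age,cal_age_lo,cal_age_hi,live_collected
PII-G4-2,Timoclea ovata,NA,NA,0.034,0.018,NA,NA,1,0.1,2,TRUE
PII-G4-3,Timoclea ovata,NA,NA,0.036,0.021,NA,NA,1,0.1,2,TRUE
PII-G4-7,Timoclea ovata,NA,NA,0.037,0.022,NA,NA,1,0.1,2,TRUE
Bri_M44-0-2-001,Timoclea ovata,0,2,0.110,0.045,NA,NA,357,198,492,FALSE
Bri_M44-12-14-001,Timoclea ovata,12,14,0.130,0.035,NA,NA,338,182,488,FALSE
Bri_M44-12-14-002,Timoclea ovata,12,14,0.230,0.087,NA,NA,3363,3213,3506,FALSE
Bri_M44-20-25-001,Timoclea ovata,20,25,0.155,0.041,NA,NA,573,486,685,FALSE
Bri_M44-20-25-004,Timoclea ovata,20,25,0.160,0.042,NA,NA,558,459,681,FALSE
Bri_M44-20-25-005,Timoclea ovata,20,25,0.206,0.064,NA,NA,2080,1922,2236,FALSE
Bri_M44-30-35-012,Timoclea ovata,30,35,0.206,0.063,NA,NA,1577,1435,1736,FALSE
Bri_M44-50-55-029,Timoclea ovata,50,55,0.240,0.070,NA,NA,2274,2119,2401,FALSE
Bri_M44-130-135-002,Timoclea ovata,130,135,0.272,0.097,NA,NA,5981,5810,6152,FALSE
Bri_M44-130-135-012,Timoclea ovata,130,135,0.359,0.152,NA,NA,9092,8854,9308,FALSE
Bri_M44-130-135-015,Timoclea ovata,130,135,0.289,0.110,NA,NA,6428,6305,6582,FALSE
Bri_M44-150-155-004,Timoclea ovata,150,155,0.316,0.118,NA,NA,7807,7675,7954,FALSE
Bri_M44-150-155-006,Timoclea ovata,150,155,0.334,0.137,NA,NA,8807,8603,9036,FALSE
Bri_M44-115-120-A1,Arca noae,115,120,NA,NA,NA,NA,5466,5352,5616,FALSE
Bri_M44-110-115-G1,Glycymeris sp.,110,115,NA,NA,NA,NA,7807,7675,7954,FALSE
Bri_M44-110-115-P1,Pecten sp.,110,115,NA,NA,NA,NA,6040,5918,6226,FALSE
Bri_M44-105-110-O1,Ostrea sp.,105,110,NA,NA,NA,NA,6253,6063,6369,FALSE
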