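id,structure,metric,dose_gy,volume_pct,unit,direction,bound,minor_lo,minor_hi,in_penalty
V40Gy_CTV,ctv,V,40,,pct,lower,95,90,,FALSE
V36.25Gy_PTV,ptv,V,36.25,,pct,lower,95,90,,TRUE
D98pct_PTV,ptv,D,,98,Gy,lower,34.4,,,TRUE
V36Gy_rectum,rectum,V,36,,cc,upper,2,,,TRUE
V29Gy_rectum,rectum,V,29,,pct,upper,20,,,FALSE
V18.1Gy_rectum,rectum,V,18.1,,pct,upper,50,,,FALSE
V37Gy_bladder,bladder,V,37,,cc,upper,10,,,TRUE
V18.1Gy_bladder,bladder,V,18.1,,pct,upper,40,,,FALSE
V18.1Gy_bowel,bowel,V,18.1,,cc,upper,5,,,FALSE
V30Gy_bowel,bowel,V,30,,cc,upper,1,,,FALSE
V14.5Gy_femoral_heads,femoral_heads,V,14.5,,pct,upper,5,,,FALSE
V29.5Gy_penile_bulb,penile_bulb,V,29.5,,pct,upper,50,,,FALSE
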