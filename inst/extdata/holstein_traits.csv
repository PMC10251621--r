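trait,reliability,heritability,genetic_sd,weight_old,weight_new
RZM,0.743,0.314,12,0.45,0.36
RZN,0.673,0.090,12,0.20,0.18
RZEo,0.638,0.194,12,0.15,NA
RZEn,0.717,0.194,12,NA,0.15
RZR,0.541,0.013,12,0.10,0.07
RZKm,0.635,0.049,12,0.03,0.015
RZKd,0.604,0.033,12,NA,0.015
RZH,0.720,0.061,12,NA,0.18
RZC,0.499,0.014,12,NA,0.03
RZS,0.764,0.273,12,0.07,NA
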