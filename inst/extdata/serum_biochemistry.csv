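# Serum biochemical parameters (mean and SD per group) for the acute
# restraint-stress rat experiment: non-stressed controls (n = 6) vs stressed
# animals (n = 7). Values are group summary statistics suitable for
# pooled-variance t-tests from summaries.
analyte,unit,mean_nonstressed,sd_nonstressed,n_nonstressed,mean_stressed,sd_stressed,n_stressed
total_protein,g/L,43.65,7.36,6,43.73,2.22,7
albumin,g/L,25.20,3.43,6,24.21,0.74,7
globulin,g/L,18.45,4.15,6,19.51,1.52,7
albumin_globulin_ratio,ratio,1.39,0.17,6,1.25,0.06,7
total_bilirubin,umol/L,2.45,1.04,6,1.97,0.25,7
direct_bilirubin,umol/L,1.45,1.14,6,0.69,0.13,7
indirect_bilirubin,umol/L,1.00,0.20,6,1.28,0.15,7
alt,U/L,39.50,14.60,6,36.40,9.60,7
ast,U/L,134.50,43.02,6,145.28,24.55,7
ast_alt_ratio,ratio,3.57,1.06,6,4.07,0.49,7
ggt,U/L,0.10,0.04,6,0.18,0.26,7
alp,U/L,231.33,59.86,6,252.18,54.72,7
triglycerides,mmol/L,1.07,0.78,6,0.93,0.48,7
total_cholesterol,mmol/L,1.86,0.34,6,1.79,0.11,7
hdl,mmol/L,0.51,0.09,6,0.53,0.05,7
ldl,mmol/L,0.15,0.05,6,0.15,0.02,7
glucose,mmol/L,4.93,0.58,6,3.37,0.27,7
ldh,U/L,1070.77,410.95,6,1395.87,183.29,7
bun,mmol/L,3.82,1.56,6,4.48,0.84,7
creatinine,umol/L,39.33,12.97,6,44.13,2.80,7
bun_creatinine_ratio,ratio,0.10,0.02,6,0.10,0.01,7
uric_acid,umol/L,164.67,78.32,6,104.58,26.78,7
total_bile_acid,umol/L,33.60,19.64,6,52.73,47.84,7
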