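treatment,yield_kg_ha,wue_kg_m3,applied_m3_ha,applied_reduction_pct
BI,30000,4.01,NA,NA
NSI,35000,7.14,3455,42.8
TSFI,32000,5.24,NA,22.7
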