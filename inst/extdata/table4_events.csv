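treatment,event,Q_lps,t_min,Ig_mm,In_mm,AE_pct
BI,1,8.71,150,95,29.9,31.2
NSI,1,8.61,93,74.3,57.5,77.4
TSFI,1,7.25,110,129,78.9,66.7
BI,2,10.30,200,149.8,27.8,26.2
NSI,2,8.62,82,86.7,64.4,74.3
TSFI,2,9.26,94,123.1,79.5,61.6
BI,3,10.63,220,170.2,33.3,28.1
NSI,3,8.65,80,91.2,65,69.3
TSFI,3,9.23,90,108.4,73,51.2
BI,4,10.53,250,205.7,44.8,21.8
NSI,4,8.15,68,93.3,71.6,64.8
TSFI,4,9.15,80,100.6,55.5,45
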