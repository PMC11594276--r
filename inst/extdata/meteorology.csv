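variable,stage,HL,YC,YN,QTX,HSP
temperature_C,germination,9.90,9.57,10.67,10.67,8.33
temperature_C,flowering,20.23,19.88,20.88,20.78,17.68
temperature_C,coloring,25.38,25.05,26.04,25.90,22.65
temperature_C,maturation,20.15,19.78,20.69,20.53,17.45
humidity_pct,germination,36.13,36.21,36.58,37.14,40.42
humidity_pct,flowering,33.62,33.71,34.42,35.24,40.20
humidity_pct,coloring,38.20,38.06,38.61,39.33,44.78
humidity_pct,maturation,42.94,43.26,44.83,46.38,53.94
precipitation_mm,germination,11.02,12.07,14.43,14.70,19.74
precipitation_mm,flowering,20.46,18.41,18.75,19.40,23.81
precipitation_mm,coloring,23.82,26.37,26.25,31.81,43.40
precipitation_mm,maturation,29.03,26.36,22.00,25.18,29.33
sunshine_h,germination,171.98,171.14,175.58,177.56,187.51
sunshine_h,flowering,211.67,210.28,214.17,214.53,215.71
sunshine_h,coloring,209.89,208.46,212.49,213.97,220.32
sunshine_h,maturation,157.65,154.11,154.43,152.27,157.43
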