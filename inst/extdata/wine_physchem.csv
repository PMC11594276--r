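sample,region,is_average,residual_sugar_gL,residual_sugar_sd,residual_sugar_letter,titratable_acid_gL,titratable_acid_sd,titratable_acid_letter,pH,pH_sd,pH_letter,alcohol_pctvol,alcohol_sd,alcohol_letter
HL1,HL,FALSE,3.03,0.06,c,5.31,0.04,bc,3.54,0.01,c,12.87,0.03,c
HL2,HL,FALSE,4.13,0.06,a,5.74,0.01,a,3.55,0.01,bc,13.72,0.04,b
HL3,HL,FALSE,3.10,0.10,c,5.22,0.04,cd,3.60,0.01,a,12.85,0.00,c
HL4,HL,FALSE,2.87,0.23,c,5.08,0.17,d,3.60,0.04,a,12.81,0.01,c
HL5,HL,FALSE,3.73,0.15,b,5.45,0.02,b,3.59,0.01,ab,14.10,0.03,a
Average HL,HL,TRUE,3.37,0.51,A,5.36,0.24,AB,3.58,0.03,AB,13.27,0.56,A
YC1,YC,FALSE,3.67,0.15,a,5.17,0.03,d,3.48,0.00,d,12.26,0.02,b
YC2,YC,FALSE,3.13,0.15,b,5.43,0.04,c,3.55,0.00,b,12.02,0.02,c
YC3,YC,FALSE,2.83,0.06,c,5.83,0.02,a,3.46,0.01,e,10.53,0.03,d
YC4,YC,FALSE,3.20,0.10,b,4.38,0.01,e,3.63,0.00,a,12.29,0.06,b
YC5,YC,FALSE,3.17,0.15,b,5.62,0.05,b,3.50,0.01,c,14.37,0.03,a
Average YC,YC,TRUE,3.20,0.30,A,5.29,0.52,AB,3.52,0.06,B,12.29,1.27,BC
YN1,YN,FALSE,3.27,0.15,b,5.32,0.03,bc,3.60,0.01,a,13.35,0.02,b
YN2,YN,FALSE,3.87,0.15,a,5.67,0.03,a,3.50,0.01,d,12.85,0.04,c
YN3,YN,FALSE,3.10,0.10,bc,5.36,0.03,b,3.59,0.01,a,13.95,0.03,a
YN4,YN,FALSE,2.87,0.06,c,4.94,0.01,d,3.54,0.01,b,12.48,0.05,d
YN5,YN,FALSE,3.17,0.06,b,5.27,0.03,c,3.52,0.01,c,12.29,0.02,e
Average YN,YN,TRUE,3.25,0.36,A,5.31,0.24,AB,3.55,0.04,AB,12.99,0.63,AB
QTX1,QTX,FALSE,3.07,0.12,bc,5.41,0.01,b,3.57,0.01,d,12.51,0.05,d
QTX2,QTX,FALSE,3.17,0.06,bc,4.97,0.03,d,3.61,0.00,c,13.50,0.03,b
QTX3,QTX,FALSE,3.40,0.17,b,5.51,0.02,a,3.52,0.00,e,12.82,0.04,c
QTX4,QTX,FALSE,4.17,0.12,a,4.44,0.03,f,3.49,0.01,f,11.86,0.08,f
QTX5,QTX,FALSE,2.90,0.10,c,4.66,0.03,e,3.63,0.00,b,12.24,0.01,e
QTX6,QTX,FALSE,3.20,0.17,bc,5.20,0.01,c,3.74,0.01,a,15.89,0.11,a
Average QTX,QTX,TRUE,3.32,0.43,A,5.03,0.40,B,3.59,0.08,A,13.14,1.37,AB
HSP1,HSP,FALSE,3.07,0.06,bc,5.21,0.04,d,3.41,0.00,d,12.23,0.03,b
HSP2,HSP,FALSE,3.10,0.00,bc,5.52,0.02,b,3.47,0.01,a,10.73,0.01,d
HSP3,HSP,FALSE,2.97,0.15,c,5.94,0.02,a,3.44,0.00,c,12.41,0.02,a
HSP4,HSP,FALSE,3.20,0.10,b,5.41,0.03,c,3.45,0.01,b,11.50,0.02,c
HSP5,HSP,FALSE,3.43,0.06,a,5.91,0.03,a,3.34,0.01,e,12.42,0.03,a
Average HSP,HSP,TRUE,3.15,0.18,A,5.60,0.30,A,3.42,0.05,C,11.86,0.68,C
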