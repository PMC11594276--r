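category,cas,formula,name,conc_min_ugL,conc_max_ugL,slope,intercept,r2
C6 Compounds,111-27-3,C6H14O,Hexanol,100,1600,1.2458,-0.0375,0.9643
C6 Compounds,66-25-1,C6H12O,Hexanal,10,160,8.0136,0.011,0.9997
C6 Compounds,928-95-0,C6H12O,(E)-2-Hexenol,10,160,2.4937,-0.009,0.9986
C6 Compounds,928-94-9,C6H12O,(Z)-2-Hexenol,10,160,2.6556,-0.0033,0.9981
C6 Compounds,6728-26-3,C6H10O,(E)-2-Hexenal,100,1600,3.3488,0.8776,0.9972
C6 Compounds,142-83-6,C6H8O,"(E,E)-2,4-Hexadienal",10,160,5.3355,-0.0463,0.9946
Alcohols,111-87-5,C8H18O,Octanol,10,160,51.698,-0.5564,0.9957
Alcohols,143-08-8,C9H20O,1-Nonanol,10,160,71.56,-1.2978,0.9913
Alcohols,123-96-6,C8H18O,2-Octanol,10,160,35.682,-0.5183,0.9861
Alcohols,3391-86-4,C8H16O,1-Octen-3-ol,10,160,24.777,-0.1763,0.9982
Alcohols,111-70-6,C7H16O,1-Heptanol,10,160,22.935,-0.1722,0.9963
Alcohols,123-51-3,C5H12O,3-Methyl-1-butanol,10,160,4.2804,-0.1309,0.9473
Alcohols,626-89-1,C6H14O,4-Methyl-1-pentanol,10,160,2.1821,0.2708,0.9911
Alcohols,104-76-7,C8H18O,2-Ethylhexanol,10,160,52.137,-0.4486,0.9967
Alcohols,60-12-8,C8H10O,Phenethyl alcohol,10,160,4.4301,-0.2658,0.9537
Alcohols,589-98-0,C8H18O,3-Octanol,10,160,38.532,0.8656,0.9944
Alcohols,100-51-6,C7H8O,Benzyl alcohol,10,160,3.3507,-0.1344,0.9955
Alcohols,137-32-6,C5H12O,2-Methyl-1-butanol,100,1600,7.0677,-0.0259,0.9991
Alcohols,543-49-7,C7H16O,2-Heptanol,10,160,5.8322,0.446,0.9918
Esters,123-86-4,C6H12O2,Butyl acetate,10,160,6.2698,-0.0748,0.9852
Esters,142-92-7,C8H16O2,Hexyl acetate,10,160,77.214,-2.5275,0.9922
Esters,119-36-8,C8H8O3,Methyl salicylate,10,160,33.87,-1.4589,0.9913
Esters,93-58-3,C8H8O2,Methyl benzoate,10,160,43.754,-1.3116,0.9918
Esters,141-32-2,C7H12O2,Butyl acrylate,10,160,42.2,-0.8667,0.9926
Esters,141-78-6,C4H8O2,Ethyl acetate,100,1600,0.027,-0.0002,0.9964
Esters,105-54-4,C6H12O2,Ethyl butyrate,10,160,29.542,-0.6768,0.9914
Esters,123-92-2,C7H14O2,Isoamyl acetate,10,160,36.549,-0.6111,0.9927
Esters,123-66-0,C8H16O2,Ethyl hexanoate,10,160,163.94,-3.9053,0.9961
Esters,106-32-1,C10H20O2,Ethyl caprylate,10,160,229.85,-6.9287,0.9948
Esters,123-25-1,C8H14O4,Diethyl succinate,10,160,13.16,-0.5471,0.9915
Esters,111-11-5,C9H18O2,Caprylic acid methyl ester,10,160,179.14,-6.1591,0.9921
Esters,638-11-9,C7H14O2,Isopropyl butyrate,10,160,13.046,-0.3695,0.9948
Esters,624-41-9,C7H14O2,2-Methylbutyl acetate,100,1600,102.51,-0.0826,0.9971
Esters,105-66-8,C7H14O2,Propyl butyrate,10,160,54.77,-0.8899,0.996
Esters,37064-20-3,C8H16O2,Natural propyl 2-methylbutyrate,10,160,86.527,-2.316,0.9949
Esters,112-06-1,C9H18O2,Heptyl acetate,10,160,142.01,-5.8118,0.9916
Esters,623-42-7,C5H10O2,Methyl butyrate,10,160,10.822,0.6266,0.9983
Esters,868-57-5,C6H12O2,Methyl 2-methylbutyrate,10,160,13.384,-0.1074,0.9969
Esters,7452-79-1,C7H14O2,Ethyl 2-methylbutyrate,10,160,67.904,-0.5643,0.9972
Esters,15706-73-7,C9H18O2,Butyl 2-methylbutanoate,10,160,167.71,-6.1318,0.9943
Aldehydes,111-71-7,C7H14O,Heptanal,10,160,29.74,0.0397,0.9982
Aldehydes,124-13-0,C8H16O,Octanal,10,160,125.84,-2.0365,0.9934
Aldehydes,124-19-6,C9H18O,Nonanal,10,160,28.958,-0.0203,0.9972
Aldehydes,100-52-7,C7H6O,Benzaldehyde,10,160,12.281,-0.1913,0.9974
Aldehydes,18829-55-5,C7H12O,(E)-2-Heptenal,10,160,23.382,0.1089,0.9989
Aldehydes,2548-87-0,C8H14O,(E)-2-Octenal,10,160,66.898,-1.1385,0.9975
Aldehydes,4313-03-5,C7H10O,"(E,E)-2,4-Heptadienal",10,160,16.991,-0.1225,0.9996
Aldehydes,5910-87-2,C9H14O,"(E,E)-2,4-Nonadienal",10,160,32.147,-0.9573,0.9921
Aldehydes,112-31-2,C10H20O,Decanal,10,160,259.53,-10.679,0.9923
Aldehydes,18829-56-6,C9H16O,(E)-2-Nonenal,10,160,145.84,-5.5835,0.9927
Aldehydes,557-48-2,C9H14O,"(E,Z)-2,6-Nonadienal",10,160,47.523,-1.0794,0.9998
Terpenes,99-83-2,C10H16,alpha-Phellandrene,10,160,152.44,-3.4687,0.9985
Terpenes,123-35-3,C10H16,beta-Myrcene,10,160,141.09,-2.865,0.9971
Terpenes,106-25-2,C10H18O,Nerol,10,160,35.863,-0.6729,0.9937
Terpenes,16409-43-1,C10H18O,(Z)-Rose oxide,10,160,209.19,-4.503,0.9982
Terpenes,78-70-6,C10H18O,Linalool,10,160,79.016,-0.1611,0.9941
Terpenes,562-74-3,C10H18O,4-Terpinenol,10,160,69.579,-0.3551,0.9995
Terpenes,98-55-5,C10H18O,alpha-Terpineol,10,160,46.539,-0.6597,0.9965
Terpenes,106-22-9,C10H20O,Citronellol,10,160,67.36,-1.497,0.9972
Terpenes,106-24-1,C10H18O,Geraniol,10,160,29.682,-0.3935,0.9939
Terpenes,87-44-5,C15H24,beta-Caryophyllene,10,160,189.71,-8.1006,0.9924
Terpenes,536-59-4,C10H16O,Dihydro cuminyl alcohol,10,160,11.437,-0.2996,0.9951
Terpenes,99-49-0,C10H14O,Carvone,10,160,63.254,-2.057,0.9951
Terpenes,5989-27-5,C10H16,D-Limonene,10,160,189.67,-1.6892,0.9928
Terpenes,99-87-6,C10H14,p-Cymene,10,160,171.9,-1.0382,0.9967
Terpenes,502-61-4,C15H24,Farnesene,10,160,69.691,-3.4768,0.9871
C13-Norisoprenoids,23696-85-7,C13H18O,beta-Damascenone,10,160,148.1,-3.6408,0.9911
C13-Norisoprenoids,689-67-8,C13H22O,Geranylacetone,10,160,276.85,-8.7723,0.9926
C13-Norisoprenoids,79-77-6,C13H20O,beta-Ionone,10,160,88.038,-1.3341,0.9989
C13-Norisoprenoids,4312-99-6,C8H14O,1-Octen-3-one,10,160,48.416,-0.3725,0.9973
C13-Norisoprenoids,98-86-2,C8H8O,Acetophenone,10,160,17.348,-0.4572,0.9925
C13-Norisoprenoids,1604-28-0,C8H12O,"6-Methyl-3,5-heptadiene-2-one",10,160,18.08,-0.3982,0.9974
C13-Norisoprenoids,110-93-0,C8H14O,6-Methyl-5-hepten-2-one,10,160,26.734,0.4244,0.9955
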