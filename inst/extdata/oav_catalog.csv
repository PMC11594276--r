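no,cas,name,threshold_ugL,threshold_matrix,aroma_description,type,HL,YC,YN,QTX,HSP
1,104-67-6,Undecan-4-olide,2.1,a,"Fruity, creamy",fruity,4.69,4.69,4.84,4.71,4.71
2,105-54-4,Ethyl butyrate,20,b,"Apple, pineapple",fruity,1.70,1.75,2.39,1.72,2.17
3,105-68-0,Isoamyl propionate,8.6,a,Tropical fruit,fruity,1.46,1.44,1.60,1.54,1.65
4,106-30-9,Ethyl heptanoate,18,c,"Fruity, cognac, rum",fruity,0.99,1.00,1.00,1.03,1.22
5,106-32-1,Ethyl caprylate,5,b,Fruity,waxy,29.24,34.24,29.38,23.21,39.27
6,106-33-2,Ethyl laurate,20,b,"Sweet, waxy, flower",waxy,1.94,2.15,1.13,1.41,1.46
7,106-70-7,Methyl hexanoate,10,a,"Fruity, bacon",fruity,1.13,1.21,1.33,1.18,1.35
8,108-64-5,Ethyl isovalerate,3,c,"Fruity, sweet, apple, pineapple",fruity,4.93,4.33,5.73,5.39,6.68
9,110-19-0,Isobutyl acetate,40,d,"Fruity odor, mild characteristic ester flavor",fruity,0.58,1.18,1.33,0.70,0.78
10,111-27-3,1-Hexanol,1100,c,Gentle sweetness,herbal,1.02,1.15,1.05,0.97,1.73
11,111-82-0,Methyl laurate,1.5,e,"Wax, soapy, coconut, mushroom",waxy,7.70,7.60,6.77,6.92,7.18
12,112-12-9,2-Undecanone,5.5,a,Fruity flavor,fruity,2.19,2.12,2.07,2.14,2.15
13,112-31-2,Decanal,1.25,f,Pleasant smell,solvent,11.10,11.13,11.36,0.00,0.00
14,112-54-9,Dodecanal,0.29,a,Flower fragrance,solvent,47.20,47.21,48.04,47.34,47.98
15,116-53-0,2-methyl-Butanoic acid,100,a,"Spicy, sour, goat milk cheese",solvent,1.88,1.72,1.26,1.78,1.83
16,122-78-1,Benzeneacetaldehyde,1,f,"Hyacinths, green",green,11.56,10.83,12.20,12.61,9.73
17,123-66-0,Ethyl Hexanoate,5,c,"Sweet, fruity",fruity,16.44,19.37,19.41,15.27,27.25
18,123-92-2,Isoamyl acetate,30,b,Banana flavor,fruity,7.38,9.84,11.10,7.71,12.18
19,124-06-1,Ethyl myristate,2,b,Violet,waxy,7.35,7.70,6.13,6.27,6.50
20,124-13-0,Octanal,2.5,f,"Fat, citrus",solvent,2.17,0.00,2.20,2.19,2.05
21,124-19-6,Nonanal,1,f,"Cured, peas",solvent,4.07,4.43,4.43,4.52,5.19
22,18829-56-6,(E)-2-Nonenal,0.6,f,"Fat, cucumber, aldehydes, citrus",fatty,20.90,0.00,0.00,0.00,20.97
23,23726-93-4,beta-Damascenone,0.05,g,"Apple, rose, honey, tobacco, sweet",fruity,245.43,279.35,278.00,239.98,305.44
24,35854-86-5,(6Z)-Nonen-1-ol,1,a,Cucumber,green,8.63,7.28,7.75,8.12,9.20
25,3777-69-3,2-Pentyl-Furan,5.8,a,Fruity flavor,fruity,1.81,1.78,1.75,1.77,1.81
26,432-25-7,Beta-cyclocitral,3,a,"Herbs, rose oxide, tobacco, fruity",herbal,4.49,4.48,4.49,4.48,4.52
27,5405-41-4,Ethyl 3-hydroxybutyrate,20,b,"Fruity, grapes",fruity,0.77,0.83,0.00,0.72,1.18
28,56805-23-3,"(E,Z)-3,6-Nonadien-1-ol",3,a,Fruity,green,2.18,0.00,2.16,2.16,0.00
29,6066-49-5,3-N-Butylphthalide,10,a,"Herbs, phenol, celery",herbal,1.00,1.00,1.01,1.00,1.02
30,64187-83-3,Ethyl 3Z-Hexenoate,10,e,Apple,green,1.55,1.60,1.50,1.64,1.79
31,706-14-9,gamma-Decalactone,0.7,b,"Coconut butter, sweet",fruity,0.00,0.00,14.11,14.16,0.00
32,7452-79-1,Ethyl 2-methylbutyrate,2,c,"pungent, green apple, fruity",fruity,3.01,2.71,3.17,2.83,3.38
33,79-77-6,trans-beta-Ionone,0.007,a,"Flowers, berries",floral,760.12,770.81,771.37,752.16,813.99
34,821-55-6,2-Nonanone,10.9,a,"Soil, herb",fruity,1.02,1.01,1.15,1.12,1.21
35,88-29-9,Versalide,2.4,a,Musk,musk,4.34,4.32,4.33,4.33,4.35
36,97-62-1,Ethyl isobutyrate,15,b,Wine,fruity,1.23,0.81,1.03,1.61,1.73
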