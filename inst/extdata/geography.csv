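region,winery,altitude_m,latitude,longitude
HL,Sunshine winery,1199.8,38.7127,106.0671
HL,Chateau HaiYueRenHe,1174.8,38.7113,106.0754
HL,Domaine Charme,1195.4,39.7135,106.0702
HL,Jade Vineyard,1180.4,38.7238,106.0838
HL,Hejinzun Winery,1202.1,38.7269,106.0776
YC,Legacy Peak Estate,1151.6,38.4411,106.0002
YC,Chateau Baoshi,1171.5,38.5720,106.0254
YC,Chateau Lanny,1153.6,38.6526,106.0534
YC,Chateau Mihope,1183,38.6228,106.0182
YC,Yuanshi Vineyard,1192.4,38.5826,106.0145
YN,LiLan Winery,1198.9,38.2759,105.9642
YN,Chateau Greatwall Terroir,1211.6,38.3807,105.9543
YN,Fei Tswei winery,1147.1,38.3739,105.9874
YN,Xinhunbin Winery,1145,38.2405,106.0277
YN,Chateau Yuquan of Ning Xia State Farm,1142.6,38.2627,106.0426
QTX,Xige Estate,1232,38.0769,105.8448
QTX,Zhongzexiban Winery,1230.1,38.0402,105.8397
QTX,Chateau Modern,1208.5,38.0950,105.8657
QTX,Sweet Dew Vineyard,1171.2,38.1270,105.9359
QTX,Huangkou Winery,1184.6,38.0754,105.8978
QTX,Longyu Estate,1205.28,38.0470,105.5407
HSP,Xingyu Winery,1480.1,37.3405,106.1685
HSP,Roland Margo,1482.5,37.3176,106.1640
HSP,Baoyuan Dadi Winery,1512.7,37.3052,106.1780
HSP,Chateau J.L. Jiangyuan,1456.2,37.3395,106.1567
HSP,Mingyu Winery,1454,37.3494,106.1587
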