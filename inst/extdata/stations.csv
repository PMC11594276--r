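region,location,longitude,latitude
HL,"Hongguang Town, Helan County, Yinchuan City",106.05,38.75
HL,"Hongguang Town, Helan County, Yinchuan City",106.15,38.75
HL,"Hongguang Town, Helan County, Yinchuan City",106.05,38.85
YC,"Beibao Town, Xixia District, Yinchuan City",106.05,38.65
YC,"Beibao Town, Xixia District, Yinchuan City",106.05,38.55
YC,"Beibao Town, Xixia District, Yinchuan City",105.95,38.65
YN,"Huangyangtan Farm, Yongning County, Yinchuan City",106.05,38.45
YN,"Huangyangtan Farm, Yongning County, Yinchuan City",106.05,38.35
YN,"Huangyangtan Farm, Yongning County, Yinchuan City",105.95,38.35
QTX,"Qujing Town, Qingtongxia City, Wuzhong City",105.95,38.15
QTX,"Daba Town, Qingtongxia City, Wuzhong City",105.95,38.05
QTX,"Daba Town, Qingtongxia City, Wuzhong City",105.85,38.05
HSP,"Xinzhuangji Township, Hongsibu District, Wuzhong City",106.15,37.25
HSP,"Xinzhuangji Township, Hongsibu District, Wuzhong City",106.15,37.35
HSP,"Xinzhuangji Township, Hongsibu District, Wuzhong City",106.25,37.35
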