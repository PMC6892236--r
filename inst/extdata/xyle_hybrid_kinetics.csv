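enzyme,km_mg_ml,vmax_umol_min_mg,kcat_s,kcat_over_km_ml_s_mg,specific_activity_u_mg
XYL10C,0.54,3600,2400,4400,3200
XylE,0.75,680,430,570,610
XylE-M3,0.61,1390,860,1340,1310
XylE-M6,0.42,1160,740,1760,1150
XylE-M9,0.46,1390,900,1960,1130
XylE-M3/M6,0.62,2200,1410,2280,2010
XylE-M3/M9,0.42,880,570,1370,730
XylE-M6/M9,0.57,1280,820,1440,1270
XylE-M3/M6/M9,0.67,1760,1170,1750,1500
XYL10C-M3,NA,NA,NA,NA,NA
XYL10C-M6,2.02,2530,1890,940,1830
XYL10C-M9,NA,NA,NA,NA,NA
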