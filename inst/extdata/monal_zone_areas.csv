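zone,role,zone_area_km2,suitable_km2
Wenchuan,county,3589,852
Baoxing,county,3124,544
Lixian,county,4325,401
Xiaojin,county,5568,235
Lushan,county,1259,159
Tianquan,county,2390,150
Dayi,county,1207,80
Kangding,county,1666,37
Chongzhou,county,803,19
Luding,county,647,13
Qionglai,county,1377,0
Dujiangyan,county,303,0
Wolong,reserve,2124,585
Miyaluo,reserve,1951,181
Heishuihe,reserve,325,146
Siguniangshan,reserve,583,131
Caopo,reserve,517,128
Fengtongzhai,reserve,403,111
Labahe,reserve,239,69
Anzihe,reserve,110,18
Jintangkongyu,reserve,242,0
Zhailong,reserve,204,0
reserves_total,reserve_total,6698,1364
region_total,region,26258,2490
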