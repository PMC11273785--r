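name,region,area,population_65plus,institutions,employees,professionals,beds,age_le35,age_36_45,age_46_55,age_ge56,edu_junior_college,edu_bachelor_plus
Beijing,eastern,1.64,2912060,584,20283,17127,112848,3814,4022,8860,3587,3017,1825
Tianjin,eastern,1.2,2045692,399,7401,5895,63235,1344,2446,2448,1163,960,824
Hebei,eastern,18.88,10387937,1726,29535,23494,231981,6177,8849,9978,4531,4076,1828
Liaoning,eastern,14.86,7417481,2035,19241,12953,178035,3534,5748,6854,3105,2667,1230
Shanghai,eastern,0.63,4049012,669,29193,22550,139355,2824,6129,12402,7838,3396,2006
Jiangsu,eastern,10.72,13726531,2470,46882,37418,442975,11756,12697,15204,7225,8513,5060
Zhejiang,eastern,10.35,8566349,1752,26607,19896,335694,4888,7466,9146,5107,3231,1795
Fujian,eastern,12.14,4609999,640,8759,6304,84312,1828,2293,2829,1809,1330,835
Shandong,eastern,15.79,15364078,2190,38359,30636,358829,9668,11989,11627,5075,8184,4744
Guangdong,eastern,17.97,10813000,1891,32041,24906,251597,6504,8894,12153,4490,4618,3386
Hainan,eastern,3.54,1051500,48,1136,850,9002,356,315,397,68,159,94
Inner Mongolia,western,118.3,3138918,677,8185,5874,77560,1542,2663,2959,1021,1453,740
Chongqing,western,8.24,5473605,927,12083,8805,102560,2142,2748,4667,2526,1847,806
Guangxi,western,23.76,6114117,567,12883,10180,91148,3754,3941,3661,1527,3280,1832
Sichuan,western,48.6,14167600,2541,21202,12005,297638,4838,6892,6609,2863,3879,1517
Guizhou,western,17.61,4456455,988,6731,3592,84344,2031,2317,1827,556,1552,745
Yunnan,western,39.41,5073259,880,7667,5891,89142,2352,2688,2142,485,1427,954
Tibet,western,122.84,206963,23,433,349,4160,295,122,14,2,39,31
Shaanxi,western,20.56,5266597,735,12276,9179,105009,3779,3771,3345,1381,2709,1329
Gansu,western,42.58,3147817,268,3301,2255,29049,1013,1358,763,167,783,359
Qinghai,western,72,514093,64,702,474,6734,163,331,197,11,95,71
Ningxia,western,6.64,692824,112,1792,1344,20033,475,711,483,123,338,292
Xinjiang,western,166,2005885,374,5688,4682,49562,1617,1992,1702,377,1016,461
Shanxi,middle,15.67,4504674,665,8807,5793,72262,2238,2768,2645,1156,1456,653
Jilin,middle,18.74,3757224,1498,17686,11544,136103,1573,4175,10809,1129,795,496
Heilongjiang,middle,47.3,4972868,1709,16584,12430,165563,3414,5980,5418,1772,2040,976
Anhui,middle,14.01,9159411,2452,24169,15725,360892,4467,7347,8410,3945,3470,1441
Jiangxi,middle,16.69,5371021,1808,16476,10987,166742,2498,3943,5845,4190,2030,708
Henan,middle,16.7,13401904,3244,34404,23959,310535,6253,9611,12058,6482,4061,1993
Hubei,middle,18.59,8424339,1841,25095,15436,280387,4128,10127,7411,3429,3343,1374
Hunan,middle,21.18,9842067,2381,22584,16364,225080,4832,7483,7563,2706,4307,2337
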