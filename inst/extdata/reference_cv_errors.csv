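framework,fold,rmse,mae,mape
GPSV,1,3.5064,2.3835,0.1364
GPSV,2,3.482,3.0951,0.1454
GPSV,3,3.2648,2.8499,0.1267
GPSV,4,3.6154,3.1792,0.1542
GPSV,5,2.5508,2.2965,0.1109
GPSV,6,2.2724,1.7919,0.079
GPSV,7,4.115,3.6825,0.1788
GPSV,8,2.8204,2.659,0.1277
GPSV,9,5.7247,4.0523,0.1999
GPSV,10,3.0707,2.7852,0.1334
GPLSV,1,5.2634,4.197,0.2149
GPLSV,2,4.6628,3.1899,0.1305
GPLSV,3,3.4819,2.8121,0.1491
GPLSV,4,3.1611,2.7837,0.1385
GPLSV,5,2.1046,1.8884,0.0898
GPLSV,6,2.162,2.1246,0.0994
GPLSV,7,3.3545,3.0199,0.1524
GPLSV,8,3.9891,3.725,0.18
GPLSV,9,2.2805,1.7733,0.0812
GPLSV,10,2.8879,2.4838,0.1214
GPWLSV,1,4.2408,3.4782,0.1695
GPWLSV,2,3.3293,2.8178,0.124
GPWLSV,3,3.0657,2.4178,0.1188
GPWLSV,4,3.3027,2.9839,0.1466
GPWLSV,5,1.3125,1.1388,0.0529
GPWLSV,6,1.9272,1.4114,0.0618
GPWLSV,7,2.9412,2.7196,0.1311
GPWLSV,8,2.7899,2.6865,0.1284
GPWLSV,9,2.6758,2.3282,0.1092
GPWLSV,10,3.0313,2.8014,0.1335
GPLWLSV,1,3.9132,3.1026,0.1561
GPLWLSV,2,3.2506,2.8334,0.1258
GPLWLSV,3,2.7307,2.4334,0.1075
GPLWLSV,4,2.9976,2.3738,0.1216
GPLWLSV,5,1.2192,1.1111,0.053
GPLWLSV,6,0.718,0.6497,0.0313
GPLWLSV,7,2.5167,2.1156,0.1036
GPLWLSV,8,2.0709,1.9636,0.0914
GPLWLSV,9,2.1757,1.9467,0.0916
GPLWLSV,10,2.4163,2.0302,0.1007
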