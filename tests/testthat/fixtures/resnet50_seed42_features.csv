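index,value
19,20.31477847
22,202.128109
29,8.463058111
37,0.9292175597
39,107.1378
40,407.2142689
84,116.3372226
86,48.99676656
105,3.120273246
111,0.2079807874
126,0.4793190664
127,0
129,230.7625854
130,132.0585486
135,75.2843785
140,284.0009755
193,0.9841913084
219,78.82954032
229,33.84317227
233,18.735807
247,26.37722837
248,181.1600485
252,185.1595642
270,169.6508459
271,445.3461759
273,129.086088
282,2.17633721
285,62.18013932
287,835.9714222
299,10.91484393
305,4.338214729
316,14.898507
326,86.49815578
327,44.04262169
329,334.1573299
330,27.04106675
343,284.4186588
355,427.6506867
358,11.01875833
359,326.0303898
361,24.77909455
369,7.406746234
375,49.94295753
377,92.23551131
378,21.8940272
382,280.3099195
403,17.97350762
408,82.43712825
413,6.338576404
418,262.3305141
419,195.6768246
421,492.1885551
423,73.23614962
435,396.0238864
451,552.7017702
465,123.5116209
467,15.77117555
471,22.61661662
485,63.62103421
487,0
499,32.88615341
500,56.08725419
501,181.8259841
504,0
511,45.95904563
526,464.8896708
532,69.64057464
536,7.987606269
537,5.682533198
554,396.5177731
556,1.295341892
557,31.76791573
573,3.873265339
576,84.25137325
577,2.491987908
582,11.13590677
597,0.7940105336
604,246.9455929
614,329.1031937
619,37.03145858
620,2.687443225
634,226.0095293
642,273.7602519
645,295.689962
650,1.907624512
664,4.953950372
672,149.4338046
679,26.97101561
686,35.54556327
693,8.973685292
719,79.94051271
729,384.6863871
733,365.1459404
737,0
751,177.5581286
758,667.7293646
761,29.90554363
785,59.91230098
801,0.2524267299
810,158.8274287
811,136.3894625
812,355.9329113
818,129.771867
838,0
843,0
851,160.5551233
852,31.63697956
855,127.8961709
858,188.9043474
867,0
874,22.35766008
878,33.65955429
889,174.6670632
912,208.7285893
930,70.10342011
931,244.1576515
955,26.00162019
975,7.9126562
981,248.9329168
983,344.1274164
987,690.2723015
988,357.3462443
989,365.5877211
990,26.07350452
996,313.8666528
997,116.6203202
998,119.9514283
1017,0
1023,214.2013454
1025,0
1040,176.3033275
1053,17.39308364
1064,408.4249518
1065,0
1067,176.9115058
1069,248.0658676
1072,123.9309753
1073,172.2396126
1075,490.3485437
1089,3.850145102
1101,263.5317776
1127,354.8789613
1128,302.3436943
1129,191.5285689
1134,2.836106905
1145,134.4364119
1148,304.7168832
1154,19.80017751
1162,541.1968217
1165,130.2548041
1167,1.615993126
1169,267.0722357
1200,457.7914286
1211,19.75452929
1218,190.3900604
1222,53.46709287
1238,1.48377048
1242,113.9666597
1266,463.9625668
1301,85.61267549
1304,60.76117929
1314,129.2123989
1317,289.7693675
1319,0
1328,252.3976974
1331,149.8708852
1340,34.21550763
1350,144.7140827
1363,33.3776728
1369,23.77776036
1370,0
1380,326.6183845
1395,1.800536814
1414,132.2862414
1426,206.9056903
1428,12.93320803
1446,127.5872974
1464,58.44616217
1466,219.4227743
1475,300.6588424
1481,1.944500567
1507,92.34589358
1514,400.405017
1516,47.05860755
1518,0.0798314813
1522,232.9306277
1530,60.11276393
1532,49.96140765
1533,6.902341221
1536,3.064851026
1549,0.3432470865
1550,235.4574209
1567,425.5006586
1569,31.37251443
1572,347.328794
1589,200.3028905
1611,6.289303548
1614,574.9589452
1615,562.2787542
1625,326.6091198
1634,537.784597
1639,452.2345099
1640,23.84112499
1646,46.81129007
1652,14.3253886
1654,20.50220758
1685,199.3806737
1696,469.7128242
1699,26.06958462
1701,459.9789467
1706,181.9774436
1708,58.31031164
1740,79.27032388
1742,292.0630351
1748,11.69120636
1749,51.55305444
1753,643.1183381
1760,46.89781842
1766,244.0967805
1773,171.0829849
1791,439.2792954
1799,3.596055489
1801,395.4679152
1815,293.9851013
1820,48.00188688
1826,261.8676347
1832,4.005176926
1836,211.2606012
1840,0
1841,480.9240535
1843,480.4027892
1854,425.7192417
1860,449.8245417
1862,194.0345936
1865,275.0540851
1871,229.9519883
1891,225.377078
1895,312.3039265
1898,58.98599421
1919,857.7598989
1923,101.8490673
1930,200.4060887
1932,1.615715979
1942,82.20785823
1948,341.8286059
1949,87.27913844
1961,77.03314808
1964,63.08159072
1974,110.9582292
2002,4.457478201
2003,1.373964021
2004,647.4111327
2006,32.20843038
2017,99.89019831
2030,19.96238729
2045,1.131956827
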