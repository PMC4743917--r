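-0.3334
-0.7268
-0.0669
0.0716
0.4116
0.2440
0.3533
0.3778
0.1684
-0.5733
0.1282
0.1656
0.1782
-0.1507
0.2879
-0.1919
-0.3288
-0.1417
-0.2123
-0.0344
-0.2380
0.7603
0.1147
0.1037
-0.1018
0.7810
0.2296
0.0742
-0.3974
-0.5157
0.0291
-0.3231
-0.3846
0.0164
-0.2835
0.3917
-0.5732
-0.2017
-0.0523
-0.1358
2.3076
1.2980
1.5784
2.5114
1.6760
1.3919
2.0941
2.1962
2.0406
1.6852
1.5942
2.1518
2.1277
2.4785
1.7885
2.3805
2.3223
1.8270
1.4186
1.5022
2.0158
2.4385
1.8867
2.3336
1.9956
2.1038
2.2500
2.2317
2.1129
1.9183
1.7668
1.7408
2.4688
2.5009
2.0967
1.2241
2.3331
1.9978
2.0333
1.8721
0.9004
0.0725
1.0152
0.4418
0.8374
0.2945
0.4708
0.4166
0.4616
0.9864
1.2230
1.1513
0.4375
1.3799
0.7276
0.8546
0.3277
0.3020
0.7359
0.6066
0.6249
0.9633
0.8444
0.0441
0.5640
0.5109
0.5792
1.0825
0.3795
0.6875
0.2126
0.2438
1.0639
0.2416
0.0709
0.0986
1.4560
0.0087
0.5027
0.3765
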