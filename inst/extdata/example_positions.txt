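5
49
172
201
229
283
338
342
418
433
484
488
498
512
540
619
666
703
720
733
795
832
862
885
890
904
925
938
940
967
998
1012
1061
1091
1126
1147
1150
1173
1176
1249
1261
1297
1311
1454
1486
1530
1531
1644
1670
1690
1717
1773
1797
1824
1864
1911
1925
1936
1998
2034
2161
2352
2384
2413
2574
2630
2638
2900
3002
3102
3124
3185
3242
3246
3254
3341
3439
3456
3485
3729
3782
3821
3867
4009
4026
4194
4245
4266
4368
4383
4418
4424
4445
4462
4503
4519
4606
4640
4653
4752
4800
4949
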