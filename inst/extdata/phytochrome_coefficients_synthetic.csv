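# Synthetic phytochrome photoconversion coefficient table.
# Relative photoconversion cross-sections of the Pr (sigma_r) and Pfr
# (sigma_fr) forms, built from smooth Gaussian absorption bands (Pr: red
# band at 666 nm, minor blue band; Pfr: far-red band at 730 nm with red
# and blue shoulders) and scaled to reproduce the photoequilibria that
# published coefficient sets give for narrow-band LED sources.
# Regenerate with tools/make_phytochrome_table.R.
wavelength_nm,sigma_r,sigma_fr
380,0.05488,0.025398
382,0.059463,0.027009
384,0.064221,0.028653
386,0.069137,0.03032
388,0.074188,0.032006
390,0.079353,0.033702
392,0.084604,0.0354
394,0.089913,0.037092
396,0.095248,0.03877
398,0.100576,0.040423
400,0.105863,0.042043
402,0.11107,0.043621
404,0.116162,0.045148
406,0.1211,0.046613
408,0.125846,0.048009
410,0.130363,0.049326
412,0.134614,0.050556
414,0.138566,0.051691
416,0.142184,0.052723
418,0.145439,0.053647
420,0.148304,0.054455
422,0.150756,0.055144
424,0.152773,0.055708
426,0.154342,0.056144
428,0.155449,0.05645
430,0.15609,0.056624
432,0.156262,0.056666
434,0.155967,0.056577
436,0.155213,0.056358
438,0.154013,0.056012
440,0.152383,0.055543
442,0.150343,0.054955
444,0.147918,0.054253
446,0.145136,0.053443
448,0.142028,0.052533
450,0.138626,0.05153
452,0.134966,0.050441
454,0.131085,0.049276
456,0.127021,0.048044
458,0.122811,0.046753
460,0.118495,0.045412
462,0.114108,0.044031
464,0.109688,0.04262
466,0.10527,0.041187
468,0.100886,0.039742
470,0.096568,0.038293
472,0.092343,0.036847
474,0.088238,0.035414
476,0.084275,0.034
478,0.080474,0.032612
480,0.076853,0.031257
482,0.073424,0.029939
484,0.070198,0.028664
486,0.067184,0.027436
488,0.064386,0.026258
490,0.061806,0.025134
492,0.059445,0.024066
494,0.0573,0.023055
496,0.055368,0.022102
498,0.05364,0.021209
500,0.052111,0.020374
502,0.050771,0.019598
504,0.04961,0.01888
506,0.048618,0.018217
508,0.047783,0.017608
510,0.047093,0.017052
512,0.046537,0.016546
514,0.046104,0.016087
516,0.045782,0.015673
518,0.045562,0.0153
520,0.045432,0.014966
522,0.045385,0.014667
524,0.045413,0.014402
526,0.04551,0.014165
528,0.04567,0.013955
530,0.045892,0.013769
532,0.046173,0.013603
534,0.046515,0.013455
536,0.046921,0.013322
538,0.047397,0.013202
540,0.04795,0.013092
542,0.048592,0.01299
544,0.049336,0.012895
546,0.050198,0.012804
548,0.051198,0.012715
550,0.052359,0.012628
552,0.053705,0.012542
554,0.055266,0.012455
556,0.057071,0.012366
558,0.059153,0.012276
560,0.061549,0.012185
562,0.064296,0.012092
564,0.067431,0.011998
566,0.070994,0.011905
568,0.075025,0.011813
570,0.079562,0.011725
572,0.084645,0.011643
574,0.09031,0.011569
576,0.096592,0.011507
578,0.103525,0.011461
580,0.111139,0.011437
582,0.119463,0.011438
584,0.128521,0.011473
586,0.138339,0.011546
588,0.148938,0.011667
590,0.160341,0.011843
592,0.172569,0.012084
594,0.185648,0.012399
596,0.199604,0.0128
598,0.214467,0.013298
600,0.230275,0.013903
602,0.247071,0.014627
604,0.264905,0.015483
606,0.283834,0.016482
608,0.303922,0.017635
610,0.325241,0.018953
612,0.347864,0.020445
614,0.371867,0.022118
616,0.397322,0.023981
618,0.424294,0.026037
620,0.452834,0.028289
622,0.482976,0.030737
624,0.514724,0.03338
626,0.548053,0.036211
628,0.582894,0.039224
630,0.619133,0.04241
632,0.656605,0.045755
634,0.695087,0.049248
636,0.734296,0.052871
638,0.773891,0.056611
640,0.813473,0.060451
642,0.852587,0.064377
644,0.890733,0.068376
646,0.927371,0.072439
648,0.961935,0.07656
650,0.993846,0.080738
652,1.022529,0.084979
654,1.047426,0.089296
656,1.068014,0.093707
658,1.083823,0.098242
660,1.094451,0.102938
662,1.099578,0.10784
664,1.098975,0.113002
666,1.092518,0.118485
668,1.080192,0.124358
670,1.062089,0.130693
672,1.038414,0.137567
674,1.009473,0.145058
676,0.975669,0.153242
678,0.937491,0.162191
680,0.895494,0.17197
682,0.850293,0.182634
684,0.802537,0.194225
686,0.752895,0.206769
688,0.70204,0.22027
690,0.65063,0.234714
692,0.599293,0.250061
694,0.548614,0.266246
696,0.499122,0.28318
698,0.451287,0.300743
700,0.405506,0.318794
702,0.362104,0.337163
704,0.321335,0.355661
706,0.283378,0.374077
708,0.248344,0.392186
710,0.216282,0.409751
712,0.187181,0.426528
714,0.160983,0.44227
716,0.137586,0.456739
718,0.116855,0.469703
720,0.098628,0.480946
722,0.082724,0.490274
724,0.068953,0.497519
726,0.057118,0.502542
728,0.047021,0.505238
730,0.03847,0.505539
732,0.031281,0.503415
734,0.02528,0.498874
736,0.020306,0.491962
738,0.016213,0.482765
740,0.012869,0.471401
742,0.010154,0.458022
744,0.007966,0.442807
746,0.006215,0.425959
748,0.004822,0.4077
750,0.003722,0.388263
752,0.002858,0.367892
754,0.002184,0.346834
756,0.001662,0.32533
758,0.00126,0.303617
760,0.000952,0.281919
762,0.000717,0.260447
764,0.000539,0.23939
766,0.000405,0.21892
768,0.000305,0.199185
770,0.000229,0.180309
772,0.000173,0.162393
774,0.000131,0.145514
776,1e-04,0.129727
778,7.7e-05,0.115065
780,6e-05,0.101542
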