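"wavelength","irradiance"
350,0.96
351,0.94523
352,0.93564
353,0.93085
354,0.9305
355,0.93418
356,0.94154
357,0.95217
358,0.96572
359,0.98179
360,1
361,1.01994
362,1.04105
363,1.06273
364,1.08437
365,1.10538
366,1.12517
367,1.14312
368,1.15864
369,1.17113
370,1.18
371,1.18482
372,1.18591
373,1.18377
374,1.1789
375,1.17178
376,1.16292
377,1.15282
378,1.14196
379,1.13086
380,1.12
381,1.10994
382,1.10145
383,1.09537
384,1.09252
385,1.09374
386,1.09987
387,1.11172
388,1.13014
389,1.15596
390,1.19
391,1.23264
392,1.28237
393,1.33723
394,1.39526
395,1.4545
396,1.51297
397,1.56873
398,1.61979
399,1.6642
400,1.7
401,1.72579
402,1.74244
403,1.7514
404,1.75411
405,1.75201
406,1.74656
407,1.73919
408,1.73134
409,1.72446
410,1.72
411,1.71902
412,1.72108
413,1.72538
414,1.73111
415,1.73744
416,1.74359
417,1.74873
418,1.75205
419,1.75274
420,1.75
421,1.7433
422,1.73332
423,1.721
424,1.70731
425,1.69321
426,1.67964
427,1.66759
428,1.65799
429,1.6518
430,1.65
431,1.65328
432,1.66133
433,1.67358
434,1.68949
435,1.70848
436,1.72999
437,1.75346
438,1.77833
439,1.80403
440,1.83
441,1.85574
442,1.88098
443,1.90551
444,1.92913
445,1.95162
446,1.97279
447,1.99242
448,2.0103
449,2.02623
450,2.04
451,2.05146
452,2.06068
453,2.06781
454,2.07296
455,2.07628
456,2.0779
457,2.07794
458,2.07655
459,2.07386
460,2.07
461,2.06513
462,2.05957
463,2.05364
464,2.04767
465,2.04201
466,2.03699
467,2.03294
468,2.03021
469,2.02911
470,2.03
471,2.03305
472,2.03784
473,2.0438
474,2.05036
475,2.05693
476,2.06295
477,2.06784
478,2.07103
479,2.07194
480,2.07
481,2.06482
482,2.05674
483,2.04627
484,2.03395
485,2.02028
486,2.00578
487,1.99099
488,1.97641
489,1.96258
490,1.95
491,1.9391
492,1.92992
493,1.92238
494,1.91642
495,1.91197
496,1.90896
497,1.90733
498,1.907
499,1.90791
500,1.91
501,1.91313
502,1.91694
503,1.92099
504,1.92485
505,1.9281
506,1.93029
507,1.93101
508,1.92983
509,1.9263
510,1.92
511,1.91072
512,1.89913
513,1.88612
514,1.87258
515,1.8594
516,1.84746
517,1.83766
518,1.8309
519,1.82804
520,1.83
521,1.83729
522,1.84902
523,1.8639
524,1.88067
525,1.89807
526,1.91482
527,1.92966
528,1.94131
529,1.94852
530,1.95
531,1.94492
532,1.93416
533,1.91902
534,1.90081
535,1.88082
536,1.86037
537,1.84076
538,1.82329
539,1.80927
540,1.8
541,1.7964
542,1.79785
543,1.80334
544,1.81185
545,1.82238
546,1.83393
547,1.84547
548,1.856
549,1.86451
550,1.87
551,1.87171
552,1.86996
553,1.86531
554,1.85835
555,1.84964
556,1.83976
557,1.82929
558,1.81879
559,1.80883
560,1.8
561,1.79275
562,1.78712
563,1.78301
564,1.78035
565,1.77904
566,1.77902
567,1.78018
568,1.78246
569,1.78576
570,1.79
571,1.79506
572,1.80061
573,1.80631
574,1.81179
575,1.81669
576,1.82065
577,1.82333
578,1.82435
579,1.82336
580,1.82
581,1.81406
582,1.80596
583,1.79624
584,1.78547
585,1.77421
586,1.763
587,1.75243
588,1.74303
589,1.73536
590,1.73
591,1.72732
592,1.72699
593,1.72853
594,1.73145
595,1.73524
596,1.73941
597,1.74346
598,1.74691
599,1.74925
600,1.75
601,1.74879
602,1.74583
603,1.74146
604,1.73602
605,1.72985
606,1.72329
607,1.71669
608,1.71038
609,1.7047
610,1.7
611,1.69652
612,1.69415
613,1.69268
614,1.6919
615,1.6916
616,1.69158
617,1.69161
618,1.6915
619,1.69103
620,1.69
621,1.68824
622,1.68579
623,1.68271
624,1.67908
625,1.67498
626,1.67048
627,1.66566
628,1.66059
629,1.65534
630,1.65
631,1.64463
632,1.63926
633,1.63392
634,1.62865
635,1.62348
636,1.61842
637,1.61352
638,1.60879
639,1.60428
640,1.6
641,1.59598
642,1.59222
643,1.58871
644,1.58542
645,1.58236
646,1.57952
647,1.57687
648,1.5744
649,1.57212
650,1.57
651,1.56803
652,1.56617
653,1.56438
654,1.56261
655,1.56081
656,1.55896
657,1.55699
658,1.55487
659,1.55256
660,1.55
661,1.54718
662,1.54414
663,1.54094
664,1.53767
665,1.53438
666,1.53113
667,1.52801
668,1.52507
669,1.52237
670,1.52
671,1.51798
672,1.51624
673,1.51468
674,1.5132
675,1.51168
676,1.51003
677,1.50814
678,1.5059
679,1.50323
680,1.5
681,1.49615
682,1.49176
683,1.48694
684,1.48178
685,1.47641
686,1.47092
687,1.46542
688,1.46003
689,1.45486
690,1.45
691,1.44555
692,1.4415
693,1.43781
694,1.43447
695,1.43145
696,1.4287
697,1.42622
698,1.42396
699,1.42189
700,1.42
701,1.41824
702,1.41657
703,1.41494
704,1.41328
705,1.41155
706,1.4097
707,1.40768
708,1.40542
709,1.40288
710,1.4
711,1.39675
712,1.39318
713,1.38933
714,1.38528
715,1.38108
716,1.3768
717,1.37249
718,1.36821
719,1.36403
720,1.36
721,1.35618
722,1.35256
723,1.34914
724,1.34591
725,1.34286
726,1.33998
727,1.33726
728,1.3347
729,1.33228
730,1.33
731,1.32784
732,1.32579
733,1.32381
734,1.32189
735,1.31999
736,1.31809
737,1.31617
738,1.3142
739,1.31215
740,1.31
741,1.30773
742,1.30532
743,1.30277
744,1.30006
745,1.29719
746,1.29414
747,1.29091
748,1.28748
749,1.28385
750,1.28
751,1.27594
752,1.27172
753,1.2674
754,1.26306
755,1.25875
756,1.25454
757,1.2505
758,1.24668
759,1.24316
760,1.24
761,1.23724
762,1.23484
763,1.23272
764,1.23082
765,1.22906
766,1.22738
767,1.2257
768,1.22396
769,1.22208
770,1.22
771,1.21766
772,1.21509
773,1.2123
774,1.20935
775,1.20626
776,1.20307
777,1.19982
778,1.19653
779,1.19325
780,1.19
781,1.18682
782,1.1837
783,1.18064
784,1.17762
785,1.17464
786,1.17169
787,1.16876
788,1.16584
789,1.16292
790,1.16
791,1.15706
792,1.15412
793,1.15115
794,1.14817
795,1.14518
796,1.14217
797,1.13915
798,1.13612
799,1.13306
800,1.13
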