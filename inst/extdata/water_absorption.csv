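"wavelength","absorption"
350,0.015
355,0.0134
360,0.012
365,0.010839
370,0.01
375,0.009481
380,0.009
385,0.008325
390,0.0075
395,0.006628
400,0.0058
405,0.005091
410,0.0046
415,0.004366
420,0.0043
425,0.004331
430,0.0045
435,0.004867
440,0.0054
445,0.006044
450,0.0068
455,0.007664
460,0.0085
465,0.009161
470,0.0098
475,0.010645
480,0.0117
485,0.01294
490,0.0146
495,0.017031
500,0.0204
505,0.02477
510,0.03
515,0.035568
520,0.0402
525,0.042584
530,0.0435
535,0.044469
540,0.0467
545,0.050969
550,0.0558
555,0.059157
560,0.0615
565,0.064179
570,0.0685
575,0.075718
580,0.086
585,0.099991
590,0.123
595,0.1625
600,0.21
605,0.242522
610,0.258
615,0.266496
620,0.273
625,0.280381
630,0.289
635,0.29858
640,0.309
645,0.321125
650,0.34
655,0.36961
660,0.4
665,0.418509
670,0.43
675,0.443466
680,0.46
685,0.479962
690,0.51
695,0.557939
700,0.624
705,0.708599
710,0.827
715,1.001207
720,1.231
725,1.500032
730,1.799
735,2.111255
740,2.38
745,2.523363
750,2.47
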