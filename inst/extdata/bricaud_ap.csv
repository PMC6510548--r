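"wavelength","A","E"
370,0.043,0.75
380,0.046,0.748
390,0.05,0.745
400,0.054,0.742
410,0.059,0.74
420,0.063,0.738
430,0.065,0.733
440,0.0654,0.728
450,0.062,0.73
460,0.056,0.734
470,0.05,0.74
480,0.045,0.748
490,0.039,0.755
500,0.032,0.764
510,0.025,0.775
520,0.019,0.788
530,0.015,0.8
540,0.012,0.812
550,0.01,0.825
560,0.0082,0.836
570,0.007,0.845
580,0.0063,0.852
590,0.0058,0.858
600,0.0056,0.862
610,0.0058,0.86
620,0.0062,0.856
630,0.007,0.848
640,0.008,0.838
650,0.01,0.825
660,0.014,0.812
670,0.019,0.8
675,0.0201,0.796
680,0.019,0.8
690,0.012,0.815
700,0.006,0.83
710,0.0035,0.835
720,0.0022,0.84
730,0.0015,0.84
740,0.0011,0.84
750,9e-04,0.84
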