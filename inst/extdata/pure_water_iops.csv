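wavelength_nm,absorption_m1,backscatter_m1
380,0.011370,0.004713
390,0.008510,0.004212
400,0.006630,0.003776
410,0.004730,0.003394
420,0.004540,0.003058
430,0.004950,0.002763
440,0.006350,0.002501
450,0.009220,0.002270
460,0.009790,0.002064
470,0.010600,0.001881
480,0.012700,0.001718
490,0.015000,0.001571
500,0.020400,0.001440
510,0.032500,0.001322
520,0.040900,0.001216
530,0.043400,0.001120
540,0.047400,0.001033
550,0.056500,0.000954
560,0.061900,0.000883
570,0.069500,0.000818
580,0.089600,0.000758
590,0.135100,0.000704
600,0.222400,0.000655
610,0.264400,0.000610
620,0.275500,0.000569
630,0.291600,0.000531
640,0.310800,0.000496
650,0.340000,0.000464
660,0.410000,0.000434
670,0.439000,0.000407
680,0.465000,0.000381
690,0.516000,0.000358
700,0.624000,0.000337
710,0.827000,0.000317
720,1.231000,0.000298
730,1.799000,0.000281
740,2.380000,0.000265
750,2.470000,0.000250
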