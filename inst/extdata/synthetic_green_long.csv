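wavelength_nm,reflectance,label
300,8.1641,synthetic_green
305,7.8298,synthetic_green
310,7.6705,synthetic_green
315,7.6488,synthetic_green
320,7.7123,synthetic_green
325,7.7977,synthetic_green
330,7.8454,synthetic_green
335,7.8201,synthetic_green
340,7.7289,synthetic_green
345,7.623,synthetic_green
350,7.5803,synthetic_green
355,7.6739,synthetic_green
360,7.938,synthetic_green
365,8.3469,synthetic_green
370,8.8135,synthetic_green
375,9.2075,synthetic_green
380,9.3864,synthetic_green
385,9.2319,synthetic_green
390,8.6861,synthetic_green
395,7.7791,synthetic_green
400,6.6291,synthetic_green
405,5.4065,synthetic_green
410,4.2762,synthetic_green
415,3.3525,synthetic_green
420,2.6854,synthetic_green
425,2.2728,synthetic_green
430,2.0846,synthetic_green
435,2.0853,synthetic_green
440,2.2521,synthetic_green
445,2.5827,synthetic_green
450,3.0917,synthetic_green
455,3.8019,synthetic_green
460,4.7371,synthetic_green
465,5.9248,synthetic_green
470,7.4072,synthetic_green
475,9.2566,synthetic_green
480,11.5789,synthetic_green
485,14.4929,synthetic_green
490,18.081,synthetic_green
495,22.324,synthetic_green
500,27.0511,synthetic_green
505,31.9382,synthetic_green
510,36.5714,synthetic_green
515,40.556,synthetic_green
520,43.619,synthetic_green
525,45.6555,synthetic_green
530,46.7094,synthetic_green
535,46.9154,synthetic_green
540,46.4445,synthetic_green
545,45.4724,synthetic_green
550,44.1663,synthetic_green
555,42.6776,synthetic_green
560,41.1309,synthetic_green
565,39.6123,synthetic_green
570,38.1629,synthetic_green
575,36.7801,synthetic_green
580,35.4247,synthetic_green
585,34.0316,synthetic_green
590,32.5215,synthetic_green
595,30.8132,synthetic_green
600,28.8393,synthetic_green
605,26.5624,synthetic_green
610,23.9931,synthetic_green
615,21.2006,synthetic_green
620,18.3111,synthetic_green
625,15.4894,synthetic_green
630,12.9109,synthetic_green
635,10.7316,synthetic_green
640,9.0669,synthetic_green
645,7.9801,synthetic_green
650,7.4812,synthetic_green
655,7.5335,synthetic_green
660,8.0707,synthetic_green
665,9.0264,synthetic_green
670,10.3672,synthetic_green
675,12.1176,synthetic_green
680,14.3559,synthetic_green
685,17.177,synthetic_green
690,20.632,synthetic_green
695,24.6725,synthetic_green
700,29.1256,synthetic_green
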