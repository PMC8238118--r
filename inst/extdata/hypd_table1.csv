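pH,experiment,kapp1_s1,kapp2_s1,Eapp1_mV,Eapp2_mV,eta_rad,Gamma_pmol_cm2,lfq_1e4
4.0,1,4000,4000,-95.9,-95.2,2.13e-3,3.46,1.656
4.0,2,2034,4000,-96.9,-93.8,-2.85e-3,3.40,1.619
4.0,3,1791,4000,-98.5,-92.3,1.03e-3,3.32,1.635
5.0,1,2939,4000,-156,-149,2.26e-2,3.53,1.666
5.0,2,2175,4000,-155,-149,1.81e-3,3.57,1.594
5.0,3,4000,4000,-154,-150,-6.26e-3,3.55,1.607
6.0,1,4000,4000,-215,-206,3.64e-2,3.51,2.433
6.0,2,1888,4000,-213,-207,2.69e-2,3.56,1.684
6.0,3,4000,4000,-214,-206,1.21e-2,3.49,1.679
7.0,1,4000,4000,-273,-250,6.56e-2,4.31,1.800
7.0,2,4000,797.8,-280,-243,1.05e-1,4.18,1.692
7.0,3,4000,4000,-272,-250,5.84e-2,4.27,1.674
8.0,1,4000,4000,-314,-289,8.20e-2,4.02,1.800
8.0,2,4000,4000,-314,-288,7.77e-2,3.97,1.632
8.0,3,4000,4000,-313,-289,7.24e-2,3.97,1.642
9.0,1,4000,4000,-348,-326,5.15e-2,4.29,1.783
9.0,2,4000,4000,-348,-326,3.84e-2,4.25,1.656
9.0,3,4000,4000,-348,-326,3.24e-2,4.22,1.650
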