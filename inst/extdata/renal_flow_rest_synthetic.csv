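"time_s","flow_m3s"
0,9.3847967e-06
0.02,1.0193797e-05
0.04,1.0868402e-05
0.06,1.1389152e-05
0.08,1.1749327e-05
0.1,1.1954511e-05
0.12,1.2021043e-05
0.14,1.1973518e-05
0.16,1.1841617e-05
0.18,1.165658e-05
0.2,1.1447703e-05
0.22,1.1239191e-05
0.24,1.1047694e-05
0.26,1.0880778e-05
0.28,1.0736449e-05
0.3,1.060381e-05
0.32,1.0464733e-05
0.34,1.0296412e-05
0.36,1.0074479e-05
0.38,9.7764074e-06
0.4,9.3847967e-06
0.42,8.8902288e-06
0.44,8.2933633e-06
0.46,7.6060495e-06
0.48,6.8513126e-06
0.5,6.0621905e-06
0.52,5.2795045e-06
0.54,4.5487611e-06
0.56,3.9164629e-06
0.58,3.4261734e-06
0.6,3.1147033e-06
0.62,3.0087836e-06
0.64,3.1225404e-06
0.66,3.4560204e-06
0.68,3.9949108e-06
0.7,4.7114887e-06
0.72,5.5667189e-06
0.74,6.5133088e-06
0.76,7.4994408e-06
0.78,8.472839e-06
0.8,9.3847967e-06
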