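"time_s","pressure_pa"
0,13011.337
0.02,13346.404
0.04,13640.948
0.06,13884.171
0.08,14070.258
0.1,14198.508
0.12,14272.961
0.14,14301.605
0.16,14295.21
0.18,14265.944
0.2,14225.894
0.22,14185.661
0.24,14153.152
0.26,14132.712
0.28,14124.669
0.3,14125.343
0.32,14127.516
0.34,14121.316
0.36,14095.419
0.38,14038.453
0.4,13940.452
0.42,13794.218
0.44,13596.433
0.46,13348.423
0.48,13056.47
0.5,12731.641
0.52,12389.136
0.54,12047.207
0.56,11725.75
0.58,11444.691
0.6,11222.316
0.62,11073.717
0.64,11009.467
0.66,11034.695
0.68,11148.603
0.7,11344.509
0.72,11610.387
0.74,11929.872
0.76,12283.621
0.78,12650.913
0.8,13011.337
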