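"freq","dqe","ntf"
0,0.8,1
0.02,0.79987,0.99904
0.04,0.7994,0.99667
0.06,0.79853,0.99309
0.08,0.79723,0.98844
0.1,0.79548,0.98277
0.12,0.79326,0.97616
0.14,0.79055,0.96865
0.16,0.78735,0.9603
0.18,0.78365,0.95116
0.2,0.77944,0.94127
0.22,0.77472,0.93067
0.24,0.76948,0.9194
0.26,0.76374,0.9075
0.28,0.7575,0.89502
0.3,0.75075,0.88199
0.32,0.74351,0.86845
0.34,0.73578,0.85444
0.36,0.72757,0.84
0.38,0.7189,0.82516
0.4,0.70978,0.80996
0.42,0.70023,0.79444
0.44,0.69025,0.77863
0.46,0.67986,0.76257
0.48,0.66909,0.74629
0.5,0.65795,0.72982
0.52,0.64646,0.7132
0.54,0.63464,0.69646
0.56,0.62252,0.67962
0.58,0.61011,0.66272
0.6,0.59744,0.64578
0.62,0.58454,0.62884
0.64,0.57142,0.61192
0.66,0.55811,0.59504
0.68,0.54463,0.57823
0.7,0.53101,0.56151
0.72,0.51728,0.5449
0.74,0.50345,0.52843
0.76,0.48956,0.51211
0.78,0.47562,0.49597
0.8,0.46167,0.48001
0.82,0.44771,0.46427
0.84,0.43378,0.44874
0.86,0.4199,0.43345
0.88,0.4061,0.41841
0.9,0.39238,0.40363
0.92,0.37877,0.38912
0.94,0.36529,0.37489
0.96,0.35197,0.36095
0.98,0.33881,0.3473
1,0.32583,0.33396
1.02,0.31306,0.32093
1.04,0.3005,0.30822
1.06,0.28817,0.29582
1.08,0.27608,0.28374
1.1,0.26424,0.27199
1.12,0.25266,0.26057
1.14,0.24136,0.24946
1.16,0.23034,0.23869
1.18,0.21961,0.22824
1.2,0.20917,0.21811
1.22,0.19903,0.20831
1.24,0.1892,0.19883
1.26,0.17967,0.18966
1.28,0.17046,0.18081
1.3,0.16155,0.17227
1.32,0.15296,0.16403
1.34,0.14468,0.15609
1.36,0.13671,0.14845
1.38,0.12905,0.1411
1.4,0.1217,0.13403
1.42,0.11465,0.12724
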