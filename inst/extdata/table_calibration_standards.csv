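concentration,aCN_mean,aCN_sd,bCN_mean,bCN_sd,kCN_mean,kCN_sd,aLA_mean,aLA_sd,bLG_mean,bLG_sd,BSA_mean,BSA_sd
0.25,0.261,0.020,0.812,0.099,0.590,0.016,2.823,0.082,0.719,0.010,0.371,0.031
0.50,0.651,0.015,1.808,0.201,1.259,0.023,4.248,0.131,1.759,0.041,0.683,0.082
0.75,1.037,0.020,3.523,0.324,1.977,0.014,6.598,0.157,2.832,0.058,1.061,0.102
1.00,1.484,0.035,5.103,0.444,2.920,0.007,10.825,0.236,3.910,0.116,1.213,0.204
2.50,2.893,0.086,13.423,0.603,6.693,0.101,21.581,0.340,8.306,0.246,2.268,0.306
5.00,5.483,0.191,21.769,1.121,11.697,0.317,36.286,0.540,17.363,0.479,3.309,0.408
7.50,8.028,0.311,28.721,1.521,15.247,0.585,50.038,0.626,23.026,0.693,4.337,0.510
10.00,11.053,0.396,33.320,1.896,18.672,0.891,58.970,0.789,27.211,0.913,5.001,0.612
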