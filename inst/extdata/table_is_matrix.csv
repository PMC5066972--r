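matrix,concentration,rt_mean,rt_sd,rt_cv,response_mean,response_sd,response_cv,matrix_effect,sn
solution A,0.00,18.14,0.26,1.42,8336,548,6.57,0,1
solution A,0.10,17.69,0.04,0.20,10841067,273937,2.53,0,1158
solution A,0.20,17.69,0.04,0.20,18803577,1063155,5.65,0,2043
solution A,0.25,17.55,0.03,0.16,25659384,1028574,4.01,0,2729
solution A,0.50,17.44,0.06,0.37,49743658,1288018,2.59,0,5343
solution A,0.75,17.28,0.04,0.20,69296004,1950636,2.81,0,7453
solution A,1.00,17.25,0.00,0.00,89528068,3681300,4.11,0,9729
solution A,2.50,16.91,0.10,0.59,187397208,8633480,4.61,0,19980
solution A,5.00,16.57,0.06,0.38,309549728,2783424,0.90,0,33225
solution A,7.50,16.41,0.03,0.17,415503536,4933296,1.19,0,44772
solution A,10.00,16.07,0.00,0.00,617516960,7595616,1.23,0,66266
Jersey,0.10,17.39,0.25,1.46,9740110,56148,0.58,-10.16,983
Jersey,0.20,17.46,0.03,0.16,17026691,128301,0.75,-9.45,1729
Jersey,0.25,17.43,0.04,0.20,21101578,162358,0.77,-17.76,2168
Jersey,0.50,17.18,0.06,0.33,40613736,272784,0.67,-18.35,4173
Jersey,0.75,17.11,0.04,0.21,57280948,65996,0.12,-17.34,5930
Jersey,1.00,17.02,0.06,0.33,85657548,3627620,4.24,-4.32,8686
Jersey,2.50,16.75,0.25,1.52,168809992,3279336,1.94,-9.92,17764
Jersey,5.00,16.64,0.10,0.59,282883424,4637792,1.64,-8.61,30279
Jersey,7.50,16.43,0.10,0.61,381639168,5000000,1.31,-8.15,41390
Holstein,0.10,17.55,0.10,0.56,9118925,810674,8.89,-0.28,934
Holstein,0.20,17.46,0.03,0.16,18097231,1448261,8.00,-7.25,1899
Holstein,0.25,17.39,0.07,0.41,24715424,1993082,8.06,-5.54,2521
Holstein,0.50,17.31,0.01,0.08,46471016,2130032,4.58,-15.51,4874
Holstein,0.75,17.16,0.00,0.00,73999076,3770028,5.09,11.58,7827
Holstein,1.00,17.14,0.03,0.17,92522796,7680108,8.30,5.23,9570
Holstein,2.50,16.91,0.03,0.17,188049680,10025248,5.33,0.76,19820
Holstein,5.00,16.69,0.04,0.21,327507568,11226448,3.43,10.64,34420
Holstein,7.50,16.57,0.13,0.77,416283136,21503264,5.17,0.28,44200
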