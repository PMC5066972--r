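protein_code,observed_mass,resolution,sn,fwhm,theoretical_mass,mass_difference,error_ppm,average_only
aLA B,14176.8143,33687,666399,0.4208,14176.798,-0.0163,-1.15,FALSE
aLA B+G,14500.9142,35248,90016,0.4114,14500.902,-0.0124,-0.86,FALSE
aS1CN B-8P,23600.2457,39446,119684,0.5983,23600.472,0.2263,9.59,FALSE
aS1CN B-9P,23680.2289,39607,45101,0.5979,23680.472,0.2431,10.27,FALSE
aS2CN A-10P,25133.0447,48319,11684,0.5202,25133.343,0.2983,11.87,FALSE
aS2CN A-11P,25213.0404,42536,26278,0.5927,25213.343,0.3026,12.00,FALSE
aS2CN A-12P,25292.9669,48114,9865,0.5257,25293.343,0.3761,14.87,FALSE
aS2CN A-13P,25372.9424,48843,14009,0.5195,25373.343,0.4006,15.79,FALSE
aS2CN A-14P,25451.8891,47390,4572,0.5371,25453.343,1.4539,57.12,FALSE
bCN A1-5P,24008.2085,38719,119441,0.6201,24008.317,0.1085,4.52,FALSE
bCN A2-5P,23968.2044,38068,203125,0.6296,23968.311,0.1066,4.45,FALSE
bCN B-5P,24077.2559,40473,51676,0.5949,24077.386,0.1301,5.40,FALSE
bCN I-5P,23950.2291,33522,70663,0.7145,23950.355,0.1259,5.26,FALSE
bLG A,18354.4897,37757,353954,0.4861,18355.446,0.9563,52.10,FALSE
bLG B,18269.4593,38485,293317,0.4747,18269.409,-0.0503,-2.75,FALSE
bLG D,18268.4292,40301,23874,0.4533,18268.410,-0.0192,-1.05,FALSE
BSA,66462.5929,22050,2645,3.0142,66462.966,0.3731,5.61,TRUE
kCN A-1P,19026.5498,36763,166573,0.5175,19026.542,-0.0083,-0.44,FALSE
kCN A-2P,19106.4925,37941,83630,0.5036,19106.542,0.0495,2.59,FALSE
kCN B-1P,18994.5907,36940,184866,0.5142,18994.589,-0.0022,-0.12,FALSE
kCN B-1P+G,19650.8391,42612,18763,0.4612,19650.817,-0.0224,-1.14,FALSE
kCN B-2P,19075.5445,36427,2982,0.5237,19074.589,-0.9555,-50.09,FALSE
Myo,16940.9974,37215,74077,0.4552,16940.956,-0.0414,-2.44,FALSE
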