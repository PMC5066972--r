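protein_code,rt_no_is,response_no_is,cv_no_is,rt_is,response_is,cv_is
aLA B,15.78,501203008,2.2,15.91,24.1758,2.4
aLA B+G,13.95,2709020,2.2,14.14,0.1326,2.3
aS1CN B-8P,15.28,46743521,1.9,15.38,2.2394,3.4
aS1CN B-9P,17.88,2757610,1.4,17.89,0.1435,3.4
aS2CN A-10P,6.79,6453168,0.1,6.91,0.2907,4.0
aS2CN A-11P,7.08,11045553,0.4,7.18,0.5287,5.1
aS2CN A-12P,7.56,20480763,1.7,7.69,0.9351,2.9
aS2CN A-13P,8.03,11144854,1.2,8.14,0.5129,4.0
aS2CN A-14P,8.30,4472310,0.5,8.43,0.2273,5.3
bCN A1-5P,19.67,144641829,1.6,19.68,6.6732,2.1
bCN A2-5P,21.12,261552277,2.7,21.20,11.8123,2.1
bCN B-5P,18.76,58604908,1.4,18.82,2.7343,0.7
bCN I-5P,22.61,7497135,1.7,22.55,0.2589,2.0
bLG A,22.09,242632197,1.8,22.19,9.6131,1.0
bLG B,20.64,195728821,2.3,20.64,7.7325,0.3
bLG D,24.74,7633926,0.6,24.74,0.2813,0.8
BSA,16.53,56264133,1.5,17.05,4.9275,3.6
kCN A-1P,6.44,61070224,1.1,6.44,2.7045,0.9
kCN A-2P,8.39,8329892,0.4,8.43,0.3715,1.1
kCN B-1P,8.28,78989451,0.8,8.42,3.5399,0.5
kCN B-1P+G,7.89,4958922,0.9,7.95,0.2106,2.0
kCN B-2P,9.81,20580644,1.3,9.90,0.9046,1.6
Myo,17.91,19602569,0.8,NA,NA,NA
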