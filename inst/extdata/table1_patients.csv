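sample_id,age,group,gleason,psa_total,psa_free,ft_percent
0009315,68,BPH,,11.30,4.97,21.63
0009901,60,BPH,,9.81,10.67,19.82
0009750,74,BPH,,14.17,10.99,19.09
SH-CL,57,BPH,,7.96,7.76,8.88
0009973,70,BPH,,23.32,15.20,15.75
0010268,65,BPH,,14.38,9.18,9.52
0009994,56,BPH,,11.39,8.35,14.65
0010622,65,BPH,,10.24,9.26,13.61
SH-ZRM,62,BPH,,7.70,6.81,23.66
0010253,56,PIN,,13.11,13.88,21.13
0010244,69,PIN,,7.29,6.70,8.74
0010247,60,PIN,,7.11,5.64,22.06
0009552,69,PCa,3+3,1000.00,1000.00,9.60
0009330,79,PCa,3+3,121.00,151.00,12.45
SH-WSG,70,PCa,3+3,7.98,8.68,11.11
SH-ZHJ,73,PCa,3+3,8.41,3.85,18.72
0009245,73,PCa,3+4,80.57,76.09,22.67
0010245,65,PCa,4+3,15.13,14.60,8.15
SH-LHY,74,PCa,4+3,7.82,6.70,26.27
0009210,63,PCa,3+5,486.00,343.80,-
0010753,77,PCa,4+4,14.10,12.64,23.82
0009675,74,PCa,4+4,13.90,11.59,5.65
SH-JBL,64,PCa,4+4,424.60,555.01,-
SH-ZYX,73,PCa,4+5,33.07,29.76,21.57
0009884,70,PCa,4+5,260.50,236.28,-
0009834,69,PCa,4+5,1000.00,56.83,-
0009551,73,PCa,4+5,819.00,602.99,-
0009476,79,PCa,5+4,1000.00,1000.00,-
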