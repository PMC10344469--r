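wavelength_nm,absorber,mu_a_per_mm
450,HbO,33.6431
500,HbO,11.2108
550,HbO,23.0386
600,HbO,1.71386
650,HbO,0.197094
700,HbO,0.155319
730,HbO,0.208877
750,HbO,0.277431
760,HbO,0.313851
780,HbO,0.380263
800,HbO,0.437034
850,HbO,0.566645
900,HbO,0.641627
950,HbO,0.64484
1000,HbO,0.566645
1100,HbO,0.471312
1200,HbO,0.321349
1300,HbO,0.187453
1400,HbO,0.160674
1500,HbO,0.133895
1600,HbO,0.107116
1700,HbO,0.0803372
450,HbR,55.3213
500,HbR,11.1733
550,HbR,28.6065
600,HbR,7.86073
650,HbR,2.00843
700,HbR,0.960833
730,HbR,0.590211
750,HbR,0.752492
760,HbR,0.82908
780,HbR,0.56236
800,HbR,0.408113
850,HbR,0.370087
900,HbR,0.407577
950,HbR,0.32242
1000,HbR,0.278502
1100,HbR,0.241012
1200,HbR,0.187453
1300,HbR,0.160674
1400,HbR,0.160674
1500,HbR,0.133895
1600,HbR,0.107116
1700,HbR,0.0803372
450,water,9e-06
500,water,2.5e-05
550,water,4.5e-05
600,water,0.00022
650,water,0.00032
700,water,6e-04
750,water,0.0026
800,water,0.002
850,water,0.0043
900,water,0.0068
950,water,0.03
970,water,0.045
1000,water,0.036
1070,water,0.015
1100,water,0.02
1150,water,0.055
1200,water,0.105
1250,water,0.09
1300,water,0.13
1350,water,0.3
1400,water,1.2
1450,water,2.9
1500,water,2.1
1550,water,1.1
1600,water,0.67
1650,water,0.52
1700,water,0.55
450,fat,0.0015
500,fat,0.001
600,fat,8e-04
700,fat,7e-04
750,fat,7e-04
800,fat,8e-04
850,fat,6e-04
900,fat,0.002
930,fat,0.012
960,fat,0.004
1000,fat,0.0025
1040,fat,0.004
1100,fat,0.003
1150,fat,0.03
1210,fat,0.19
1250,fat,0.07
1300,fat,0.035
1350,fat,0.05
1400,fat,0.13
1450,fat,0.12
1500,fat,0.09
1600,fat,0.1
1700,fat,0.4
450,melanin,99.3732
500,melanin,68.8705
550,melanin,49.4296
600,melanin,36.5159
650,melanin,27.6382
700,melanin,21.3554
750,melanin,16.7972
800,melanin,13.4182
850,melanin,10.866
900,melanin,8.90605
950,melanin,7.37855
1000,melanin,6.17233
1050,melanin,5.20847
1100,melanin,4.42999
1150,melanin,3.79508
1200,melanin,3.27264
1250,melanin,2.83924
1300,melanin,2.477
1350,melanin,2.17214
1400,melanin,1.91392
1450,melanin,1.6939
1500,melanin,1.5054
1550,melanin,1.34306
1600,melanin,1.20257
1650,melanin,1.08045
1700,melanin,0.973838
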