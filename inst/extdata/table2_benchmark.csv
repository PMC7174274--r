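molecule_index,molecule_name,method,E_v_eV,f,delta_eV,Gamma_eV
1,ethene,CC2,7.16,0.082,0.07,0.192
1,ethene,CC2,7.91,0.381,0.14,0.605
2,E-butadiene,CC2,6.14,0.745,0.13,0.403
3,all-E-hexatriene,CC2,5.18,1.265,0.1,0.4
4,all-E-octatetraene,CC2,4.53,1.778,0.06,0.329
5,cyclopropene,CC2,6.75,0.075,0.02,0.771
5,cyclopropene,CC2,7.09,0.031,0.19,0.294
5,cyclopropene,CC2,7.4,0.058,0.14,0.287
6,cyclopentadiene,CC2,5.49,0.105,0.09,0.46
7,norbornadiene,CC2,5.64,0.018,0.07,0.296
7,norbornadiene,CC2,6.09,0.018,0.18,0.356
8,benzene,ADC(2),6.89,0.078,0.06,0.059
8,benzene,ADC(2),7.19,0.77,0.15,0.155
9,naphthalene,CC2,4.79,0.08,0.13,0.36
10,furan,CC2,6.39,0.185,0.1,0.328
10,furan,CC2,6.43,0.042,0,0.749
11,pyrrole,CC2,5.77,0.013,0.15,0.4
11,pyrrole,CC2,5.86,0.027,0.21,0.134
11,pyrrole,CC2,6.28,0.189,0.21,0.309
12,imidazole,CC2,6.3,0.032,0.03,0.032
12,imidazole,CC2,6.35,0.027,0,0.027
12,imidazole,CC2,6.44,0.153,0.14,0.153
13,pyridine,CC2,5.04,0.005,0.27,0.216
13,pyridine,CC2,5.32,0.032,0.05,0.278
14,pyrazine,CC2,4.18,0.006,0.14,0.213
14,pyrazine,CC2,5.14,0.085,0.05,0.229
15,pyrimidine,CC2,4.44,0.006,0.07,0.395
15,pyrimidine,CC2,5.52,0.03,0.11,0.262
15,pyrimidine,CC2,6.11,0.004,0.15,0.323
16,pyridazine,CC2,3.83,0.005,0.08,0.286
16,pyridazine,CC2,5.39,0.018,0.06,0.359
17,s-triazine,CC2,4.8,0.016,0.06,0.422
18,s-tetrazine,CC2,5.24,0.056,0.09,0.364
19,formaldehyde,CC2,6.38,0.022,0.05,0.128
20,acetone,CC2,5.74,0.031,0.08,0.226
21,p-benzoquinone,ADC(2),5.33,0.593,0.14,0.393
22,formamide,CC2,6.13,0.028,0.05,0.349
22,formamide,CC2,6.55,0.021,0.17,0.215
22,formamide,CC2,6.71,0.064,0.01,0.251
22,formamide,CC2,7.23,0.029,0.1,0.241
22,formamide,CC2,7.53,0.337,0.05,0.5
23,acetamide,CC2,5.77,0.032,0,0.452
23,acetamide,CC2,6.36,0.019,0.03,0.239
23,acetamide,CC2,6.88,0.019,0.19,0.241
23,acetamide,CC2,7.26,0.206,0.09,0.421
23,acetamide,CC2,7.6,0.056,0,0.24
24,propanamide,CC2,5.77,0.026,0.02,0.399
24,propanamide,CC2,6.36,0.02,0.08,0.247
24,propanamide,CC2,6.76,0.014,0,0.259
24,propanamide,CC2,7.19,0.189,0.16,0.394
24,propanamide,CC2,7.48,0.027,0,0.192
25,cytosine,CC2,4.68,0.05,0.08,0.412
25,cytosine,CC2,5.57,0.137,0.18,0.391
26,thymine,ADC(2),5.1,0.205,0.18,0.418
26,thymine,ADC(2),6.1,0.028,0.41,0.275
26,thymine,ADC(2),6.19,0.048,0.2,0.254
27,uracil,CC2,5.34,0.182,0.17,0.344
27,uracil,CC2,6.3,0.068,0.23,0.43
28,adenine,ADC(2),5.13,0.247,0.17,0.357
28,adenine,ADC(2),5.19,0.059,0,0.569
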