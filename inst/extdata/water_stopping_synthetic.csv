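# material=water
# density=1
# provenance=synthetic (relativistic Bethe collision stopping power plus
#   approximate radiative term; generated by data-raw/stopping_tables.R)
energy_keV,mass_tsp_MeV_cm2_per_g,mass_csda_g_per_cm2
1,120.437,4.15154e-06
1.11108,112.591,5.10608e-06
1.2345,105.115,6.24134e-06
1.37163,98.0141,7.5933e-06
1.52399,91.2885,9.20521e-06
1.69327,84.9341,1.11292e-05
1.88136,78.944,1.3428e-05
2.09034,73.309,1.61773e-05
2.32253,68.0181,1.94682e-05
2.58052,63.0591,2.34107e-05
2.86716,58.4184,2.81375e-05
3.18565,54.0823,3.38085e-05
3.53951,50.0363,4.0617e-05
3.93268,46.2659,4.87958e-05
4.36952,42.7566,5.86266e-05
4.85488,39.494,7.04489e-05
5.39416,36.4639,8.46728e-05
5.99335,33.6528,0.000101794
6.65909,31.0471,0.000122409
7.39878,28.6341,0.000147241
8.22063,26.4014,0.000177161
9.13378,24.3372,0.00021322
10.1484,22.4304,0.000256687
11.2756,20.6702,0.000309091
12.5281,19.0466,0.000372278
13.9197,17.5499,0.00044847
15.466,16.1712,0.000540344
17.1839,14.902,0.000651123
19.0927,13.7344,0.00078468
21.2135,12.6608,0.000945672
23.5699,11.6744,0.00113969
26.188,10.7687,0.00137343
29.097,9.93743,0.00165492
32.3291,9.17506,0.00199375
35.9202,8.47629,0.00240137
39.9102,7.83622,0.00289144
44.3434,7.25031,0.00348018
49.2691,6.71432,0.00418685
54.7419,6.22436,0.00503426
60.8226,5.7768,0.00604932
67.5788,5.3683,0.00726373
75.0854,4.99577,0.00871466
83.4259,4.65636,0.0104456
92.6928,4.34743,0.0125072
102.989,4.06657,0.0149583
114.429,3.81153,0.0178667
127.14,3.58028,0.0213107
141.263,3.37091,0.0253795
156.954,3.1817,0.030175
174.388,3.01105,0.0358124
193.759,2.8575,0.0424217
215.282,2.71972,0.0501482
239.196,2.59646,0.0591539
265.765,2.48661,0.0696181
295.287,2.38912,0.0817384
328.087,2.30304,0.0957308
364.531,2.2275,0.111831
405.023,2.16169,0.130295
450.013,2.10486,0.151398
500,2.05634,0.175437
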