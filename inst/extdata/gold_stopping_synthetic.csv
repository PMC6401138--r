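# material=gold
# density=19.3
# provenance=synthetic (relativistic Bethe collision stopping power plus
#   approximate radiative term; generated by data-raw/stopping_tables.R)
energy_keV,mass_tsp_MeV_cm2_per_g,mass_csda_g_per_cm2
1,12.8635,3.88698e-05
1.11108,14.7231,4.68993e-05
1.2345,16.0843,5.48909e-05
1.37163,17.0284,6.31557e-05
1.52399,17.6251,7.19339e-05
1.69327,17.9347,8.14422e-05
1.88136,18.0087,9.18974e-05
2.09034,17.8911,0.000103531
2.32253,17.6198,0.000116602
2.58052,17.2266,0.000131405
2.86716,16.7389,0.000148282
3.18565,16.1794,0.000167634
3.53951,15.5677,0.000189932
3.93268,14.9197,0.000215733
4.36952,14.249,0.000245701
4.85488,13.5667,0.00028062
5.39416,12.882,0.000321427
5.99335,12.2022,0.000369238
6.65909,11.5333,0.000425382
7.39878,10.8801,0.000491447
8.22063,10.2462,0.000569328
9.13378,9.63444,0.000661288
10.1484,9.04678,0.000770028
11.2756,8.48465,0.000898777
12.5281,7.94894,0.00105139
13.9197,7.44011,0.00123247
15.466,6.95825,0.00144752
17.1839,6.50319,0.0017031
19.0927,6.07451,0.00200702
21.2135,5.67161,0.00236862
23.5699,5.29375,0.002799
26.188,4.94008,0.00331137
29.097,4.60968,0.00392145
32.3291,4.30157,0.00464787
35.9202,4.01474,0.00551273
39.9102,3.74817,0.00654216
44.3434,3.50083,0.00776702
49.2691,3.27169,0.00922368
54.7419,3.05975,0.0109549
60.8226,2.86404,0.0130107
67.5788,2.68361,0.0154497
75.0854,2.51755,0.0183401
83.4259,2.36499,0.0217611
92.6928,2.22508,0.0258041
102.989,2.09705,0.0305746
114.429,1.98015,0.0361931
127.14,1.87366,0.0427973
141.263,1.77693,0.0505433
156.954,1.68934,0.0596068
174.388,1.6103,0.0701852
193.759,1.53928,0.0824979
215.282,1.47577,0.096788
239.196,1.41932,0.113322
265.765,1.36949,0.132392
295.287,1.3259,0.154313
328.087,1.28817,0.179426
364.531,1.25599,0.208093
405.023,1.22904,0.2407
450.013,1.20706,0.277655
500,1.18981,0.319385
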