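# material: csi
# density_g_cm3: 4.51
# provenance: APPROXIMATE power-law model; detector weighting only, not for dosimetry
# columns: energy_keV, photoelectric, compton(incoherent), rayleigh(coherent), mu_en  [cm^2/g]
# partition: Klein-Nishina incoherent with water-anchored binding correction;
#   Z^2/A-scaled coherent estimate; photoelectric as remainder of the total.
# generated by data-raw/make_material_tables.R
energy_kev,pe_cm2g,compton_cm2g,rayleigh_cm2g,mu_en_cm2g
10,189.277,0.128265,5.5982,175.503
10.5,164.872,0.12803,5.10257,153.093
11,144.53,0.127796,4.67092,134.396
11.5,127.432,0.127562,4.29262,118.667
12,112.954,0.12733,3.95917,105.336
12.5,100.608,0.127099,3.66369,93.9586
13,90.0132,0.126869,3.4006,84.1866
13.5,80.8684,0.126641,3.16529,75.7443
14,72.9319,0.126413,2.95396,68.411
14.5,66.0092,0.126186,2.76343,62.0089
15,59.9424,0.125961,2.59104,56.3935
15.5,54.6025,0.125736,2.43455,51.4465
16,49.883,0.125513,2.29203,47.0705
16.5,45.6958,0.12529,2.16187,43.1847
17,41.9675,0.125069,2.04266,39.7217
17.5,38.6364,0.124849,1.9332,36.625
18,35.6508,0.12463,1.83244,33.8471
18.5,32.9667,0.124411,1.73949,31.3476
19,30.5468,0.124194,1.65355,29.0921
19.5,28.3591,0.123978,1.57392,27.0513
20,26.3762,0.123763,1.5,25.2
20.5,24.5747,0.123549,1.43125,23.5166
21,22.9341,0.123335,1.3672,21.9822
21.5,21.4367,0.123123,1.30742,20.5805
22,20.0672,0.122912,1.25154,19.2975
22.5,18.8121,0.122701,1.19923,18.1206
23,17.6597,0.122492,1.15018,17.0391
23.5,16.5995,0.122284,1.10413,16.0433
24,15.6226,0.122076,1.06083,15.1249
24.5,14.7207,0.12187,1.02008,14.2764
25,13.887,0.121664,0.981663,13.4913
25.5,13.1149,0.12146,0.945414,12.7636
26,12.3988,0.121256,0.911169,12.0881
26.5,11.7338,0.121053,0.878782,11.4603
27,11.1154,0.120851,0.84812,10.8759
27.5,10.5395,0.12065,0.819061,10.3313
28,10.0024,0.12045,0.791495,9.82295
28.5,9.5011,0.120251,0.76532,9.348
29,9.03249,0.120053,0.740444,8.90369
29.5,8.59399,0.119855,0.716781,8.48756
30,8.18319,0.119659,0.694253,8.09739
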