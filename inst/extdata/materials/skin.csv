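# material: skin
# density_g_cm3: 1.09
# provenance: ICRU-44 skin composition, mixture rule over elemental anchors
# columns: energy_keV, photoelectric, compton(incoherent), rayleigh(coherent), mu_en  [cm^2/g]
# partition: Klein-Nishina incoherent with water-anchored binding correction;
#   Z^2/A-scaled coherent estimate; photoelectric as remainder of the total.
# generated by data-raw/make_material_tables.R
energy_kev,pe_cm2g,compton_cm2g,rayleigh_cm2g,mu_en_cm2g
10,4.45641,0.131281,0.341063,4.54623
10.5,3.84137,0.134711,0.310867,3.89931
11,3.33103,0.138053,0.284569,3.36847
11.5,2.90392,0.141313,0.261522,2.92893
12,2.54364,0.144497,0.241207,2.56199
12.5,2.23756,0.147607,0.223206,2.25333
13,1.97578,0.150649,0.207177,1.99189
13.5,1.75052,0.153625,0.192841,1.76902
14,1.55557,0.156539,0.179966,1.57791
14.5,1.38596,0.159394,0.168359,1.41312
15,1.23766,0.162193,0.157856,1.2703
15.5,1.12231,0.163716,0.148321,1.14836
16,1.01965,0.165195,0.139639,1.04146
16.5,0.927952,0.166634,0.131709,0.94738
17,0.845751,0.168033,0.124446,0.864252
17.5,0.771818,0.169396,0.117777,0.790534
18,0.705113,0.170723,0.111639,0.724936
18.5,0.644751,0.172016,0.105976,0.666375
19,0.589973,0.173277,0.10074,0.613934
19.5,0.540132,0.174507,0.0958889,0.566838
20,0.494666,0.175708,0.0913855,0.524425
20.5,0.463204,0.17647,0.0871971,0.485025
21,0.433969,0.17721,0.0832948,0.449446
21.5,0.406752,0.17793,0.0796528,0.417241
22,0.381371,0.17863,0.0762485,0.388021
22.5,0.35766,0.179311,0.0730613,0.361452
23,0.335474,0.179973,0.0700731,0.337241
23.5,0.314684,0.180618,0.0672675,0.315135
24,0.295173,0.181246,0.0646298,0.294911
24.5,0.276836,0.181858,0.0621468,0.276375
25,0.259579,0.182453,0.0598065,0.259355
25.5,0.243319,0.183034,0.0575981,0.243702
26,0.227977,0.1836,0.0555118,0.229281
26.5,0.213486,0.184152,0.0535386,0.215975
27,0.199782,0.18469,0.0516706,0.203679
27.5,0.186807,0.185216,0.0499002,0.1923
28,0.174512,0.185728,0.0482208,0.181754
28.5,0.162846,0.186228,0.0466261,0.171967
29,0.151769,0.186717,0.0451105,0.162874
29.5,0.141239,0.187194,0.0436689,0.154413
30,0.131221,0.187659,0.0422965,0.146532
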