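# material: air
# density_g_cm3: 0.001205
# provenance: compiled dry-air mass coefficients (sea level)
# columns: energy_keV, photoelectric, compton(incoherent), rayleigh(coherent), mu_en  [cm^2/g]
# partition: Klein-Nishina incoherent with water-anchored binding correction;
#   Z^2/A-scaled coherent estimate; photoelectric as remainder of the total.
# generated by data-raw/make_material_tables.R
energy_kev,pe_cm2g,compton_cm2g,rayleigh_cm2g,mu_en_cm2g
10,4.64323,0.119376,0.357397,4.742
10.5,4.0077,0.122494,0.325755,4.07082
11,3.47943,0.125533,0.298198,3.51955
11.5,3.03661,0.128498,0.274047,3.06268
12,2.66252,0.131393,0.252759,2.68093
12.5,2.34425,0.134221,0.233895,2.35956
13,2.07169,0.136987,0.217099,2.08714
13.5,1.83686,0.139693,0.202077,1.85474
14,1.6334,0.142343,0.188585,1.65531
14.5,1.4562,0.144939,0.176421,1.48323
15,1.3011,0.147484,0.165416,1.334
15.5,1.18087,0.148869,0.155425,1.20306
16,1.07369,0.150214,0.146326,1.08854
16.5,0.977783,0.151522,0.138017,0.987959
17,0.89168,0.152795,0.130406,0.899269
17.5,0.814125,0.154034,0.123418,0.820776
18,0.744056,0.15524,0.116986,0.751065
18.5,0.680568,0.156416,0.111051,0.688948
19,0.622887,0.157563,0.105565,0.633425
19.5,0.570344,0.158681,0.100481,0.583649
20,0.522365,0.159773,0.0957621,0.5389
20.5,0.489618,0.160466,0.0913731,0.499261
21,0.459116,0.16114,0.0872839,0.463391
21.5,0.430656,0.161794,0.0834675,0.430853
22,0.404057,0.162431,0.0799001,0.401271
22.5,0.379159,0.16305,0.0765603,0.374317
23,0.355818,0.163652,0.073429,0.349709
23.5,0.333906,0.164238,0.070489,0.327196
24,0.313306,0.164809,0.067725,0.306562
24.5,0.293914,0.165365,0.0651231,0.287615
25,0.275638,0.165907,0.0626707,0.270187
25.5,0.258391,0.166435,0.0603565,0.254129
26,0.242097,0.16695,0.0581703,0.239311
26.5,0.226686,0.167452,0.0561027,0.225614
27,0.212094,0.167941,0.0541451,0.212936
27.5,0.198264,0.168419,0.05229,0.201184
28,0.185142,0.168885,0.0505301,0.190275
28.5,0.172681,0.16934,0.0488591,0.180135
29,0.160837,0.169784,0.047271,0.170698
29.5,0.149568,0.170217,0.0457603,0.161904
30,0.138837,0.170641,0.0443221,0.1537
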