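# material: fibroglandular
# density_g_cm3: 1.02
# provenance: Hammerstein glandular composition, mixture rule over elemental anchors
# columns: energy_keV, photoelectric, compton(incoherent), rayleigh(coherent), mu_en  [cm^2/g]
# partition: Klein-Nishina incoherent with water-anchored binding correction;
#   Z^2/A-scaled coherent estimate; photoelectric as remainder of the total.
# generated by data-raw/make_material_tables.R
energy_kev,pe_cm2g,compton_cm2g,rayleigh_cm2g,mu_en_cm2g
10,4.3571,0.131534,0.341446,4.4548
10.5,3.75547,0.13497,0.311216,3.81964
11,3.25622,0.138318,0.284889,3.2986
11.5,2.83836,0.141585,0.261816,2.86731
12,2.48587,0.144774,0.241478,2.50735
12.5,2.18638,0.147891,0.223456,2.20465
13,1.93023,0.150938,0.20741,1.94833
13.5,1.7098,0.15392,0.193058,1.72988
14,1.51903,0.15684,0.180168,1.5426
14.5,1.35303,0.1597,0.168548,1.38117
15,1.20789,0.162504,0.158033,1.24128
15.5,1.0953,0.16403,0.148488,1.12201
16,0.995078,0.165513,0.139796,1.01747
16.5,0.905521,0.166954,0.131857,0.925472
17,0.825216,0.168356,0.124586,0.84419
17.5,0.752967,0.169721,0.11791,0.772117
18,0.687764,0.171051,0.111764,0.707989
18.5,0.628744,0.172346,0.106095,0.650744
19,0.575171,0.17361,0.100853,0.599487
19.5,0.526413,0.174842,0.0959966,0.553458
20,0.481926,0.176045,0.0914881,0.512009
20.5,0.451346,0.176809,0.087295,0.47335
21,0.422908,0.177551,0.0833883,0.438453
21.5,0.396415,0.178272,0.0797422,0.406877
22,0.37169,0.178973,0.0763341,0.378237
22.5,0.348578,0.179655,0.0731433,0.352205
23,0.326939,0.180319,0.0701518,0.328491
23.5,0.306648,0.180965,0.067343,0.306846
24,0.287595,0.181594,0.0647024,0.287051
24.5,0.269678,0.182207,0.0622166,0.268915
25,0.252809,0.182804,0.0598736,0.252267
25.5,0.236904,0.183386,0.0576627,0.236961
26,0.221892,0.183953,0.0555741,0.222865
26.5,0.207705,0.184506,0.0535987,0.209862
27,0.194282,0.185045,0.0517286,0.197851
27.5,0.181569,0.185571,0.0499562,0.186738
28,0.169516,0.186085,0.0482749,0.176442
28.5,0.158077,0.186586,0.0466784,0.166891
29,0.147209,0.187075,0.0451612,0.158019
29.5,0.136876,0.187553,0.0437179,0.149767
30,0.127041,0.18802,0.0423439,0.142082
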