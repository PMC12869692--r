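# material: adipose
# density_g_cm3: 0.95
# provenance: ICRU-44 adipose composition, mixture rule over elemental anchors
# columns: energy_keV, photoelectric, compton(incoherent), rayleigh(coherent), mu_en  [cm^2/g]
# partition: Klein-Nishina incoherent with water-anchored binding correction;
#   Z^2/A-scaled coherent estimate; photoelectric as remainder of the total.
# generated by data-raw/make_material_tables.R
energy_kev,pe_cm2g,compton_cm2g,rayleigh_cm2g,mu_en_cm2g
10,2.83184,0.132907,0.298077,2.92761
10.5,2.44398,0.136379,0.271687,2.50713
11,2.12089,0.139763,0.248704,2.16262
11.5,1.84946,0.143063,0.228561,1.87778
12,1.61965,0.146286,0.210807,1.64032
12.5,1.4237,0.149435,0.195074,1.44085
13,1.25551,0.152514,0.181066,1.27211
13.5,1.11027,0.155527,0.168537,1.12845
14,0.984122,0.158478,0.157284,1.0054
14.5,0.873985,0.161368,0.14714,0.899431
15,0.777347,0.164202,0.137961,0.807692
15.5,0.706191,0.165743,0.129628,0.729104
16,0.642456,0.167241,0.12204,0.660325
16.5,0.585159,0.168698,0.115109,0.59988
17,0.533474,0.170114,0.108762,0.54655
17.5,0.4867,0.171494,0.102933,0.499324
18,0.444241,0.172837,0.0975688,0.457357
18.5,0.405587,0.174146,0.0926195,0.419943
19,0.370301,0.175423,0.0880434,0.386482
19.5,0.338007,0.176668,0.0838036,0.35647
20,0.308377,0.177884,0.0798678,0.329476
20.5,0.28956,0.178655,0.0762072,0.305216
21,0.27194,0.179405,0.0727967,0.283279
21.5,0.255412,0.180134,0.0696138,0.263395
22,0.239884,0.180842,0.0666385,0.245332
22.5,0.225273,0.181532,0.0638531,0.228886
23,0.211503,0.182202,0.0612415,0.213882
23.5,0.198508,0.182855,0.0587895,0.200166
24,0.186228,0.183491,0.0564842,0.187604
24.5,0.174608,0.18411,0.0543142,0.176078
25,0.163599,0.184713,0.0522688,0.165483
25.5,0.153158,0.185301,0.0503387,0.155728
26,0.143242,0.185874,0.0485154,0.146732
26.5,0.133815,0.186433,0.0467909,0.138424
27,0.124845,0.186978,0.0451583,0.130739
27.5,0.1163,0.187509,0.043611,0.12362
28,0.108152,0.188028,0.0421433,0.117016
28.5,0.100375,0.188535,0.0407496,0.110883
29,0.092947,0.189029,0.0394251,0.105179
29.5,0.0858448,0.189512,0.0381651,0.0998675
30,0.0790489,0.189983,0.0369656,0.0949159
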