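time,volume
0,0
0.5,0.0675566
1,0.137451
1.5,0.178169
2,0.229226
2.5,0.276223
3,0.301544
3.5,0.34562
4,0.380552
4.5,0.411163
5,0.442276
5.5,0.468957
6,0.492683
6.5,0.524731
7,0.536344
7.5,0.562543
8,0.589016
8.5,0.605156
9,0.623758
9.5,0.643934
10,0.660881
10.5,0.676247
11,0.695988
11.5,0.710279
12,0.722998
12.5,0.732745
13,0.750449
13.5,0.762008
14,0.770045
14.5,0.790451
15,0.804634
15.5,0.824108
16,0.835893
16.5,0.845713
17,0.848205
17.5,0.856187
18,0.870744
18.5,0.889895
19,0.895537
19.5,0.90692
20,0.911772
20.5,0.918483
21,0.936282
21.5,0.941793
22,0.948104
22.5,0.961211
23,0.973339
23.5,0.981846
24,0.990772
24.5,0.993336
25,1.00731
25.5,1.01069
26,1.01934
26.5,1.03155
27,1.03664
27.5,1.04132
28,1.05367
28.5,1.05387
29,1.05926
29.5,1.07089
30,1.0765
30.5,1.0827
31,1.08806
31.5,1.09262
32,1.10732
32.5,1.10732
33,1.11977
33.5,1.11977
34,1.13098
34.5,1.13098
35,1.14187
35.5,1.14244
36,1.1548
36.5,1.1548
37,1.16662
37.5,1.16924
38,1.17255
38.5,1.1767
39,1.17847
39.5,1.18907
40,1.19345
40.5,1.20726
41,1.20726
41.5,1.21008
42,1.21545
42.5,1.21708
43,1.22436
43.5,1.22978
44,1.23895
44.5,1.24459
45,1.25233
45.5,1.25233
46,1.25493
46.5,1.25636
47,1.26144
47.5,1.26722
48,1.27569
48.5,1.2793
49,1.2793
49.5,1.2841
50,1.2899
50.5,1.291
51,1.30092
51.5,1.30296
52,1.30788
52.5,1.30871
53,1.31183
53.5,1.3145
54,1.32237
54.5,1.32237
55,1.33132
55.5,1.33865
56,1.33865
56.5,1.33865
57,1.34068
57.5,1.34303
58,1.34456
58.5,1.36173
59,1.36173
59.5,1.36173
60,1.36783
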