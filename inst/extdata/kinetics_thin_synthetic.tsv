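unbind_time_s	lysis_time_s
27.642	inf
26.093	3.9
8.006	59.642
38.049	5.106
32.311	21.599
77.447	12.443
32.981	72.99
18.799	12.083
74.972	34.765
2.755	30.997
0.696	4.551
3.242	61.369
1.073	8.972
18.142	19.127
7.021	15.439
8.812	11.224
82.623	19.374
7.622	inf
3.589	74.188
2.872	18.691
0.195	94.79
7.409	48.037
45.348	139.366
9.539	23.52
56.603	58.431
57.614	34.129
13.192	135.555
30.178	63.964
17.231	7.457
4.981	0.084
2.913	35.602
71.918	45.517
185.504	96.662
2.729	inf
22.538	inf
26.6	145.426
41.753	inf
44.015	0.175
3.031	75.051
12.952	218.402
1.21	inf
4.158	126.448
65.295	36.848
10.196	134.187
22.025	122.219
8.926	31.818
85.644	inf
35.73	86.933
24.577	112.967
13.072	46.075
22.784	79.643
47.988	20.656
46.293	4.24
6.545	9.274
13.963	61.773
14.732	41.601
23.234	80.821
17.712	38.381
25.975	14.985
26.8	21.058
14	120.399
42.476	171.675
19.326	inf
9.949	11.675
6.802	33.169
2.68	71.358
39.934	70.183
18.659	3.896
43.768	177.126
11.83	34.141
10.121	22.176
37.506	36.921
32.548	14.276
4.311	12.351
11.037	100.685
19.055	40.807
7.814	inf
41.265	inf
47.728	125.52
13.506	141.705
0.742	36.057
22.464	inf
46.707	116.363
68.601	118.086
60.493	2.072
3.491	79.954
63.022	23.342
7.622	32.424
69.692	97.947
7.875	13.931
20.07	42.256
15.263	61.198
0.29	inf
1.469	inf
39.391	50.771
38.479	34.508
20.991	34.472
16.91	4.852
25.276	32.839
15.877	54.512
7.87	2.115
21.226	54.046
38.231	81.745
6.888	51.298
5.256	1.698
35.483	20.353
22.714	6.441
8.066	100.508
79.856	0.095
32.827	124.476
24.375	73.644
40.678	inf
51.925	16.657
48.48	24.43
1.753	44.584
22.039	33.002
22.184	106.594
18.254	5.862
20.208	inf
83.592	92.551
0.991	inf
15.574	2.694
14.334	34.174
14.761	3.816
5.981	39.419
20.696	126.176
46.847	8.496
1.012	123.303
13.293	30.259
25.979	46.429
16.893	73.029
12.381	7.932
9.239	172.292
6.294	45.549
16.673	143.174
16.617	91.806
21.561	2.747
3.646	5.531
69.417	102.761
31.565	114.638
32.326	120.002
106.299	132.114
1.691	48.56
15.76	63.741
68.061	12.532
13.278	18.302
26.357	1.976
88.893	11.781
2.465	24.39
15.769	46.091
8.327	32.16
13.982	56.449
11.986	29.172
7.457	28.292
23.213	13.323
8.246	55.11
7.486	20.103
13.068	3.793
13.867	17.534
23.399	50.791
67.332	91.862
50.423	0.015
46.805	50.674
5.738	20.496
19.762	56.401
70.307	42.436
2.645	16.118
5.576	inf
34.108	9.526
4.192	12.599
31.293	7.2
26.279	18.958
36.599	16.254
39.856	inf
2.439	inf
61.703	25.105
116.911	14.681
21.958	65.143
18.404	0.167
10.316	21.774
42.716	inf
32.573	8.281
13.01	10.853
23.701	64.107
13.608	25.904
3.855	36.981
32.698	42.402
6.416	83.971
32.298	4.626
68.798	22.327
10.312	inf
20.564	34.53
23.674	46.712
12.753	49.23
27.123	119.097
55.286	4.523
83.201	17.088
59.668	inf
23.346	47.053
47.931	15.89
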