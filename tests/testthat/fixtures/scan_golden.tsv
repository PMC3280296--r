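# sample=UHRR
# method=non_amp
# replicate=1
# platform_size=50
Block	Row	Column	ProbeID	GeneID	SpotType	F_Median
1	1	1	G000040	G000040	gene	29374.1319
1	1	2	G000010	G000010	gene	367.55498
1	1	3	BLANK_00022		blank	71.5757616
1	1	4	G000009	G000009	gene	1189.19893
1	1	5	G000007	G000007	gene	16387.9865
1	1	6	BLANK_00020		blank	69.2761363
1	1	7	BLANK_00008		blank	49.9617419
1	1	8	BLANK_00011		blank	82.7395911
1	1	9	G000024	G000024	gene	471.430293
1	2	1	BLANK_00013		blank	51.4635188
1	2	2	BLANK_00004		blank	89.573722
1	2	3	G000023	G000023	gene	14933.4354
1	2	4	G000026	G000026	gene	8760.88492
1	2	5	G000043	G000043	gene	291693.59
1	2	6	G000033	G000033	gene	258769.343
1	2	7	BLANK_00007		blank	76.4528659
1	2	8	G000029	G000029	gene	38952.9731
1	2	9	BLANK_00001		blank	78.6878031
1	3	1	BLANK_00023		blank	85.2832767
1	3	2	BLANK_00003		blank	92.5992436
1	3	3	BLANK_00014		blank	98.333141
1	3	4	G000013	G000013	gene	188.590143
1	3	5	BLANK_00017		blank	103.170286
1	3	6	G000011	G000011	gene	111.389184
1	3	7	G000025	G000025	gene	252.601258
1	3	8	BLANK_00012		blank	118.23893
1	3	9	BLANK_00019		blank	74.5088696
1	4	1	G000050	G000050	gene	218623.749
1	4	2	BLANK_00015		blank	115.582216
1	4	3	G000049	G000049	gene	5744.76757
1	4	4	G000032	G000032	gene	351.337316
1	4	5	G000020	G000020	gene	161.502541
1	4	6	BLANK_00016		blank	109.034601
1	4	7	BLANK_00021		blank	103.529398
1	4	8	G000037	G000037	gene	41569.5335
1	4	9	G000046	G000046	gene	1560.773
1	5	1	G000014	G000014	gene	5215.68664
1	5	2	G000006	G000006	gene	37071.5896
1	5	3	G000027	G000027	gene	2339.54202
1	5	4	G000001	G000001	gene	23224.2434
1	5	5	G000045	G000045	gene	138422.257
1	5	6	G000017	G000017	gene	5315.86783
1	5	7	BLANK_00018		blank	80.7788198
1	5	8	G000034	G000034	gene	2628.52179
1	5	9	G000036	G000036	gene	2997.57803
1	6	1	G000021	G000021	gene	351272.238
1	6	2	G000048	G000048	gene	10454.6982
1	6	3	G000044	G000044	gene	1224.52009
1	6	4	G000031	G000031	gene	1229.43593
1	6	5	G000041	G000041	gene	33605.8422
1	6	6	BLANK_00002		blank	107.706511
1	6	7	BLANK_00024		blank	92.3172342
1	6	8	G000018	G000018	gene	4804.93307
1	6	9	BLANK_00010		blank	127.569898
1	7	1	G000005	G000005	gene	13309.1746
1	7	2	G000003	G000003	gene	471280.972
1	7	3	G000038	G000038	gene	427941.523
1	7	4	G000035	G000035	gene	2303.09266
1	7	5	G000002	G000002	gene	135.350686
1	7	6	G000004	G000004	gene	10510.0128
1	7	7	BLANK_00006		blank	98.6491683
1	7	8	G000030	G000030	gene	32363.0261
1	7	9	G000042	G000042	gene	573599.104
1	8	1	G000012	G000012	gene	4036.65982
1	8	2	G000047	G000047	gene	488028.887
1	8	3	G000008	G000008	gene	137.016446
1	8	4	G000028	G000028	gene	2365.11859
1	8	5	BLANK_00005		blank	71.451443
1	8	6	BLANK_00009		blank	88.5932044
1	8	7	G000039	G000039	gene	6836.04838
1	8	8	G000016	G000016	gene	343.313972
1	8	9	G000015	G000015	gene	427.887515
1	9	1	G000022	G000022	gene	30.7249337
1	9	2	G000019	G000019	gene	34064.8205
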