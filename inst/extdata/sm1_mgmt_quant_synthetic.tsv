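model_id	mgmt_quantity_mean	mgmt_methctrl_quantity_mean	actb_quantity_mean	actb_methctrl_quantity_mean	passage_a	pct_positive_a	n_nuclei_a	passage_b	pct_positive_b	n_nuclei_b
245127-232-R	45.23	3485.96	19228.58	12634.32	3	53.3	487	4	67.4	1310
466636-057-R	304.79	6960.94	14664.92	5018.79	3	87.1	2316	4	80.2	438
692163-330-T	5.31	2304.24	9845.77	17792.42	3	58.8	619	4	68.1	959
779769-127-R	48.82	6930.43	14496.39	12800.24	3	69	1593	4	55.6	1243
997726-040-R	7202.12	9001.98	13667.85	14507.52	3	15.3	1800	4	15.1	1924
BL0293-F563	1590.31	5291.24	10533.79	9062.54	4	83.9	551	5	15.8	2250
BL0382-F1232	6186.76	9389.36	18909.69	19606	3	88.1	886	4	87.6	546
CN0375-F725	45.41	7525.33	8690.4	10703.36	3	75.6	2001	4	74.1	1245
CN0446-F447	4.19	2302.09	7092.76	16563.63	3	72.4	1211	4	40.3	1900
LG0556-F006	43.63	9003.16	7083.81	7778.9	3	42.8	760	4	60	1925
LG0567-F671	78.82	7155.54	18177.22	9343.83	3	85.1	1729	4	77.5	2051
ST0110-F1568	15.27	7965.53	11466.88	14912.23	3	90	1774	4	63.3	1930
LG0520-F434	404.55	9844.03	18442.53	5625.5	3	58.1	2420	4	38.9	670
235635-245-T	11.13	4630.79	5265.9	19322.69	3	54.9	1159	4	58.2	1288
261386-189-R	201.48	9889.12	19046.25	12348.49	3	60	1169	4	89.1	2064
283339-068-R	83.73	9162.77	10412.25	7695.11	3	69	557	4	52.8	750
743489-274-T	86.29	4372.33	16934.44	5898.15	3	63.8	1409	4	58.6	2496
743489-281-T	48.29	3488.65	15757.06	9834.94	3	44.7	2482	4	37	523
BL0269-F402	16.36	3943.1	9923.35	5509.58	3	59.2	1810	4	72.6	2065
128128-338-R	214.8	6678.8	12586.86	5528.37	3	11.8	1110	4	10.2	1525
172845-121-B	379.55	3162.32	6475.06	16318.72	3	9.7	1923	4	11.4	1112
172845-121-T	2345.46	6714.81	5021.87	9397.96	3	3	550	4	0.5	653
172845-142-T	917	4705.19	8429.06	11061.19	3	63	2110	4	73.4	1958
174941-126-T	8.86	5118.47	6035.35	18329.58	3	46	2190	4	87.2	669
248138-237-R	31.09	3786.74	7912.41	6360.47	3	89.2	1144	4	43.5	2463
292921-168-R	17.76	3447.43	10507.04	18783.5	3	67.4	1641	4	70.7	1962
327498-153-R	9.1	7497.94	17058.68	8366.99	3	76.3	762	4	46.1	1281
349418-098-R	15.83	2626.24	12828.95	11332.32	3	41.5	2054	4	62.3	1610
521955-158-R2	38.13	9424.9	6536.18	15731.88	3	77.8	610	4	91.3	2352
521955-158-R3	48.54	7968.74	16289.93	9835.24	3	63.6	412	4	65.9	1216
521955-158-R4	13.16	5078.36	5231.12	15682.67	3	48.4	1399	4	91.1	1856
521955-158-R6	156.06	8977.46	15611.19	12939.4	3	73	1280	4	75.6	2050
521955-158-R7	3.85	3495.17	6075.19	16913.34	3	68.7	1686	4	43.3	2371
563396-261-R	6.36	3152.76	8929.87	18607.38	3	83.7	1943	4	42.4	708
625472-104-R	1129.27	2348.36	15772.26	7483.63	3	43.8	742	4	80.4	1202
782815-120-R	106.11	9436.59	13831.3	9853.09	3	85.1	532	4	79.1	636
CN0330-F216	363.82	2148.77	9925.55	19741.76	3	1.1	1340	4	7.9	699
CN0428-F1126	47.2	2871.63	17375.26	11418.77	3	45.7	1853	4	62.9	2452
LG0481-F231	9.99	2104.75	8666.63	17817.7	3	37	1266	4	62.9	2233
LG1197-F385	28.01	5018.66	11203.36	13008.55	3	64.3	877	4	92.3	2219
172845-288-R	7263.79	7580.93	17192.73	10536.4	3	91.6	549	4	48.1	1469
287614-091-R	87.3	6068.89	18670.98	7890.62	3	76.2	1555	4	79	1654
692585-246-R	93.88	6244.5	13401.72	11058.77	3	78.9	1630	4	89.5	442
746718-042-R	36.74	6975.46	10784.95	16313.32	3	46.9	2467	4	68.4	2295
997537-175-T	2319.28	6193.79	16784.64	17707.13	3	71	1708	4	78.4	1440
941425-263-T	123.32	5983.18	14194.87	5028.56	3	71.3	1634	4	80.2	811
952719-076-R	48.9	5790.27	17131.01	18286.85	3	49.7	1897	4	50.5	705
BL0479-F1894	1008.42	7566.48	16003.97	16802.5	3	2	2020	4	13.7	2304
SA0426-F1136	38.61	7871.39	14029.37	13732.43	3	36.9	1800	4	93	1337
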