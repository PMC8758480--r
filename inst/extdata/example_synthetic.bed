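chrSim	1000	2124	bg_00001	0	+	1000	1000	0	3	174,118,198,	0,308,926,
chrSim	2624	4298	bg_00002	0	+	2624	2624	0	3	502,133,105,	0,595,1569,
chrSim	4798	7042	bg_00003	0	+	4798	4798	0	5	93,213,76,134,148,	0,215,1225,1640,2096,
chrSim	7542	7943	bg_00004	0	+	7542	7542	0	2	133,106,	0,295,
chrSim	8443	11040	bg_00005	0	+	8443	8443	0	5	483,64,180,92,209,	0,696,877,1182,2388,
chrSim	11540	12230	bg_00006	0	+	11540	11540	0	2	160,53,	0,637,
chrSim	12730	13733	bg_00007	0	-	12730	12730	0	2	239,130,	0,873,
chrSim	14233	17044	bg_00008	0	+	14233	14233	0	5	84,197,96,85,82,	0,1816,2106,2253,2729,
chrSim	17544	19390	bg_00009	0	+	17544	17544	0	3	163,64,106,	0,745,1740,
chrSim	19890	22594	bg_00010	0	-	19890	19890	0	5	191,133,211,136,108,	0,1086,1494,2173,2596,
chrSim	23094	23580	bg_00011	0	+	23094	23094	0	2	257,175,	0,311,
chrSim	24080	25917	bg_00012	0	+	24080	24080	0	3	207,131,155,	0,892,1682,
chrSim	26417	28131	tgt_00001	0	-	26417	26417	0	3	197,62,141,	0,1192,1573,
chrSim	28631	30154	tgt_00002	0	-	28631	28631	0	3	104,202,84,	0,799,1439,
chrSim	30654	31719	tgt_00003	0	+	30654	30654	0	4	53,125,101,132,	0,168,694,933,
chrSim	32219	32918	tgt_00004	0	+	32219	32219	0	3	63,150,139,	0,135,560,
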