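population	dataset	group	n_samples	ancestry_pct	ancestry_se_pct	date	se	bias	date_corrected
African Americans	HapMap3	NA	49	79.4	0.3	6	1	0	6
Palestinian	HGDP-CEPH	Levant	43	9.3	0.4	34	2	1	33
Bedouin-g1	HGDP-CEPH	Levant	15	14.5	0.4	34	3	2	32
Bedouin-g2	HGDP-CEPH	Levant	30	10.1	0.4	33	2	2	31
Druze	HGDP-CEPH	Levant	41	4.4	0.4	54	7	10	44
Spain	POPRES	Southern Europe	137	2.4	0.3	55	3	0	55
Portugal	POPRES	Southern Europe	134	3.2	0.3	45	5	0	45
Sardinian	HGDP-CEPH	Southern Europe	27	2.9	0.5	96	28	25	71
Southern-Italy	POPRES	Southern Europe	121	2.7	0.3	62	6	0	62
Northern-Italy	POPRES	Southern Europe	90	1.1	0.3	154	27	-26	180
Swiss-French	POPRES	Northwest Europe	759	0.5	0.2	71	6	NA	NA
Ashkenazi Jews (IBD)	IBD	Jewish	323	2.8	0.3	91	11	NA	NA
Ashkenazi Jews	Jewish HapMap	Jewish	34	3.2	0.4	76	13	23	53
Syrian Jews	Jewish HapMap	Jewish	25	3.9	0.5	99	23	27	72
Iranian Jews	Jewish HapMap	Jewish	24	2.6	0.6	129	34	59	70
Iraqi Jews	Jewish HapMap	Jewish	36	3.8	0.5	153	22	38	115
Sephardic Greek Jews	Jewish HapMap	Jewish	39	4.8	0.4	82	8	20	62
Sephardic Turkey Jews	Jewish HapMap	Jewish	27	4.5	0.4	89	11	16	73
Italian Jews	Jewish HapMap	Jewish	27	4.9	0.5	88	19	15	73
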