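# Per-method selection-signature intervals reported on the chicken Z chromosome
# (broiler lines divergently selected for abdominal fat content; endpoints
# printed at 0.01 Mb precision). stat is the method's statistic for the top
# SNP: windowed F_ST for FST, regression p-value for EIGENGWAS, standardised
# score for XPEHH. The FST interval starting at 47.72 Mb was printed with its
# end (47.58) before its start; the end is corrected to 48.58, consistent with
# the candidate region (47.72-51.04) it belongs to -- see the note column.
method	start_mb	end_mb	top_snp	stat	gene	note
FST	0.55	0.75	rs14688003	0.56	WDR7	
FST	4.53	4.66	rs16704177	0.59		
FST	11.23	11.57	rs16781096	0.57	SLC1A3	
FST	19.81	19.95	rs14753903	0.52		
FST	21.22	21.84	rs14755170	0.66	MAST4	
FST	28.08	28.19	rs16106682	0.55	KDM4C	
FST	36.03	36.25	rs16081040	0.54	ANXA1	
FST	37.29	37.85	rs16768474	0.68	VPS13A	
FST	38.04	38.89	rs13817231	0.59	TLE4	
FST	39.22	39.45	rs14787078	0.54		
FST	40.33	40.49	rs14787751	0.57	NTRK2	
FST	47.72	48.58	rs15597824	0.59	FER	end corrected from printed 47.58 (end preceded start)
FST	50.89	51.02	rs14766378	0.73	FAM174A	
FST	52.50	52.89	rs16770232	0.53	SLC49A3	
FST	55.98	57.39	rs14751311	0.66	PCSK1	
FST	58.12	58.85	rs16758604	0.60	NR2F1	
FST	59.90	60.28	rs14748688	0.54	CETN3	
FST	71.43	71.58	rs14781326	0.55	PRR16	
EIGENGWAS	1.91	2.31	rs312273884	2.24e-07	SLC14A2	
EIGENGWAS	6.95	7.35	rs14689552	2.40e-05	KIAA1328	
EIGENGWAS	9.25	9.65	rs14784526	9.10e-07	ARHGEF39	
EIGENGWAS	13.95	14.35	rs16103326	7.97e-06	FGF10	
EIGENGWAS	16.75	17.42	rs16760225	7.23e-06	IL6ST	
EIGENGWAS	17.80	18.20	rs16099146	1.05e-06	PLK2	
EIGENGWAS	18.71	19.11	rs736458094	1.18e-05	ELOVL7	
EIGENGWAS	22.90	23.50	rs313728591	7.91e-08	IQGAP2	
EIGENGWAS	32.13	32.53	rs16108416	2.11e-05	BNC2	
EIGENGWAS	33.03	33.63	rs314666735	1.66e-05	ADAMTSL1	
EIGENGWAS	39.07	39.87	rs16781643	3.03e-06	FRMD3	
EIGENGWAS	48.33	51.04	rs314662658	6.33e-06	EFNA5	
EIGENGWAS	52.48	52.88	rs14768956	1.78e-06	PCGF3	
EIGENGWAS	53.37	53.77	rs14769714	2.52e-05	ATP5I	
EIGENGWAS	61.68	62.12	rs14774149	6.47e-07		
EIGENGWAS	62.78	63.58	rs14773275	3.68e-07	VCAN	
EIGENGWAS	63.88	64.28	rs16118182	2.81e-08	CKMT2	
EIGENGWAS	64.82	66.08	rs14774834	1.72e-07	SLC46A2	
EIGENGWAS	66.24	66.67	rs13788226	2.66e-07	DNAJC25	
EIGENGWAS	66.84	67.88	rs16775262	1.59e-06	ELAVL2	
EIGENGWAS	68.59	68.99	rs16776912	2.02e-08	MOB3B	
EIGENGWAS	69.41	70.09	rs14780063	2.38e-05		
EIGENGWAS	70.35	71.36	rs16125209	2.28e-06	ACO1	
EIGENGWAS	72.16	73.63	rs14781762	7.41e-09	KCNN2	
EIGENGWAS	78.84	79.27	rs15992604	5.72e-09	CDKN2A	
EIGENGWAS	79.67	80.45	rs14685714	1.75e-07	ZNF608	
EIGENGWAS	80.62	82.42	rs16683478	9.91e-09	PAX5	
XPEHH	65.73	67.97	rs14776247	-2.78	DNAJC25	
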