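sample_id	age	sex	rin	smoking	cause_of_death	delay_hours	origin
1	46	F	7.7	never	Digestive hemorrhage	25	Africa
2	50	F	6.8	unknown	Cerebral hemorrhage	49	European
3	59	F	7.8	current	Septic shock	27	European
4	61	F	8.1	current	Cerebral hemorrhage	16	European
5	61	F	7.4	unknown	Cerebral hemorrhage	51	European
6	68	F	5.9	never	Septic shock	26	European
7	70	F	7.4	unknown	Cerebral hemorrhage	48	European
8	72	F	8.5	never	Aortic dissection	9	European
9	75	F	6.8	past	Cardiogenic shock	11	European
10	75	F	7.5	never	Digestive hemorrhage	23	European
11	79	F	6.3	never	Septic shock	21	European
12	79	F	7.5	never	Cardiac infarction	24	European
13	81	F	6.7	never	Cardiac infarction	23	European
14	39	M	7.2	never	Cardiopulmonary stop on hypoxemia	17	European
15	50	M	6.5	never	Cerebral hemorrhage	24	European
16	52	M	8.4	current	Septic shock	27	European
17	53	M	7.9	current	Cerebral hemorrhage	16	European
18	54	M	6.6	past	Cryptococcal meningitis	22	European
19	65	M	7.7	never	Respiratory failure	43	European
20	67	M	6.5	current	Septic shock	24	European
21	69	M	7	current	Respiratory failure	48	European
22	70	M	7.3	never	Digestive hemorrhage	25	European
23	74	M	6.8	unknown	Aortic dissection	46	European
24	74	M	9	current	Septic shock lung	14	European
25	75	M	6.4	never	Septic Shock	19	European
26	79	M	6.8	current	Cardiac infarction	30	European
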