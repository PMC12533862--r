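name	median_rmsd	rank	sglt2i
Empagliflozin	1.54	1	1
Ceftriaxone	1.62	2	0
Dapagliflozin	1.66	3	1
Tobramycin	1.69	4	0
Raltitrexed	1.78	5	0
Canagliflozin	1.80	6	1
Ertugliflozin	1.91	7	1
Clindamycin	1.99	8	0
Ribavirin	2.07	9	0
Fluvastatin	2.62	10	0
Timolol	2.88	11	0
Atorvastatin	3.23	12	0
Ticagrelor	3.24	13	0
Calcitriol	3.62	14	0
Fostamatinib	4.91	15	0
Theophylline	4.96	16	0
Carbocisteine	5.06	17	0
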