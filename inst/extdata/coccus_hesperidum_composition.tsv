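region	pct_A	pct_T	pct_G	pct_C
COX1	40.0	35.8	8.8	15.3
COX2	48.9	29.7	7.8	13.6
COX3	45.0	37.0	5.4	12.6
ATP8	55.3	36.2	2.8	5.7
ATP6	49.8	34.0	3.7	12.5
ND1	25.3	56.6	12.1	6.0
ND2	50.7	34.0	5.0	10.3
ND3	54.3	32.2	3.8	9.7
ND4	22.2	62.4	10.2	5.2
ND4L	23.9	64.3	9.8	2.0
ND5	23.5	60.2	10.0	6.2
ND6	55.3	32.3	3.1	9.2
CYTB	44.1	34.6	7.4	13.9
22 tRNAs	46.7	41.1	6.2	6.0
rrnL	38.3	49.2	8.3	4.1
rrnS	36.4	46.60	10.9	6.0
2 rRNAs	37.7	48.3	9.2	4.8
Total	50.9	32.5	5.8	10.9
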