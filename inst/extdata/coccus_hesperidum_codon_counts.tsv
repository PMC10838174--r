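codon	count	rscu_published
TTA	247	3.696
TCA	116	3.114
ACA	84	2.489
GTT	91	2.233
CCA	34	2.125
GGA	38	2.054
TCT	73	1.96
CAA	30	1.935
CGA	11	1.872
TAA	11	1.833
GCA	12	1.811
ATA	463	1.798
AAA	188	1.733
TTT	413	1.721
CGT	10	1.702
GAT	49	1.69
ATT	324	1.653
TGA	47	1.649
GAA	48	1.548
GCT	10	1.509
GTA	60	1.472
TAT	130	1.469
TGT	11	1.467
AGA	53	1.423
AAT	190	1.329
CCT	21	1.312
GGT	24	1.297
CAT	25	1.282
ACT	35	1.037
AGT	32	0.859
CTT	49	0.733
CTA	48	0.718
CAC	14	0.718
TTG	47	0.703
AAC	96	0.671
GCC	4	0.604
GGG	10	0.541
TGC	4	0.533
TAC	47	0.531
GAG	14	0.452
ACC	13	0.385
CCC	6	0.375
TGG	10	0.351
TCC	13	0.349
ATC	68	0.347
CGG	2	0.34
GAC	9	0.31
TTC	67	0.279
AAG	29	0.267
ATG	52	0.202
CCG	3	0.188
TAG	1	0.167
AGG	6	0.161
GTC	6	0.147
GTG	6	0.147
GGC	2	0.108
CTC	7	0.105
ACG	3	0.089
CGC	0.5	0.085
TCG	3	0.081
GCG	0.5	0.075
CAG	1	0.065
AGC	2	0.054
CTG	3	0.045
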