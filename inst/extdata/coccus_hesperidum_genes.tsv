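gene	start	end	strand	anticodon	start_codon	stop_codon	intergenic_published
trnM	753	818	+	CAU			
trnW	810	870	+	UCA			-9
COX1	861	2387	+		ATA	TAA	-10
trnL2	2388	2449	+	UAA			0
COX2	2450	3113	+		ATA	T	0
trnK	3114	3183	+	UUU			0
trnD	3180	3244	+	GUC			-4
ATP8	3238	3378	+		ATT	TAA	-7
ATP6	3372	3989	+		ATG	TAA	-7
COX3	3991	4752	+		ATG	TAA	1
trnG	4752	4809	+	UCC			-1
ND3	4807	5145	+		ATA	TAA	-3
trnA	5146	5203	-	UGC			0
trnR	5202	5249	+	UCG			-2
trnN	5241	5294	+	GUU			-9
trnS1	5296	5343	+	UCU			1
trnE	5352	5405	+	UUC			8
trnF	5396	5452	-	GAA			-10
ND5	5451	7055	-		ATT	TAA	-2
trnH	7056	7112	-	GUG			0
ND4	7114	8388	-		ATT	TAA	1
ND4L	8401	8655	-		ATT	TAA	12
ND6	8696	9172	+		ATT	TAG	40
trnP	9179	9241	+	UGG			6
trnQ	9238	9295	-	UUG			-4
trnC	9295	9349	-	GCA			-1
trnI	9359	9423	+	GAU			-10
ND2	9424	10362	+		ATT	TAA	0
trnY	10373	10425	+	GUA			10
trnT	10440	10493	+	UGU			14
CYTB	10501	11568	+		ATA	TAA	7
trnS2	11570	11622	+	UGA			1
ND1	11647	12552	-		ATT	TAA	24
trnL1	12553	12615	-	UAG			0
rrnL	12616	13789	-				0
trnV	13790	13835	-	UAC			0
rrnS	13836	14447	-				0
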