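chr1	lncage	transcript	1001	2200	.	+	.	gene_id "RG1"; transcript_id "RG1.1"; biotype "protein_coding";
chr1	lncage	exon	1001	1400	.	+	.	gene_id "RG1"; transcript_id "RG1.1"; biotype "protein_coding";
chr1	lncage	exon	1601	2200	.	+	.	gene_id "RG1"; transcript_id "RG1.1"; biotype "protein_coding";
chr1	lncage	transcript	10001	12400	.	-	.	gene_id "RG2"; transcript_id "RG2.1"; biotype "protein_coding";
chr1	lncage	exon	10001	10400	.	-	.	gene_id "RG2"; transcript_id "RG2.1"; biotype "protein_coding";
chr1	lncage	exon	10901	11300	.	-	.	gene_id "RG2"; transcript_id "RG2.1"; biotype "protein_coding";
chr1	lncage	exon	11801	12400	.	-	.	gene_id "RG2"; transcript_id "RG2.1"; biotype "protein_coding";
chr1	lncage	transcript	20001	21500	.	+	.	gene_id "RG3"; transcript_id "RG3.1"; biotype "protein_coding";
chr1	lncage	exon	20001	21500	.	+	.	gene_id "RG3"; transcript_id "RG3.1"; biotype "protein_coding";
chr1	lncage	transcript	30001	30600	.	+	.	gene_id "RL1"; transcript_id "RL1.1"; biotype "annotated_noncoding";
chr1	lncage	exon	30001	30600	.	+	.	gene_id "RL1"; transcript_id "RL1.1"; biotype "annotated_noncoding";
chr1	lncage	transcript	40001	40700	.	-	.	gene_id "RL2"; transcript_id "RL2.1"; biotype "annotated_noncoding";
chr1	lncage	exon	40001	40700	.	-	.	gene_id "RL2"; transcript_id "RL2.1"; biotype "annotated_noncoding";
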