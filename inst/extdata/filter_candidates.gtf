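chr1	lncage	transcript	1001	2200	.	+	.	gene_id "XG01"; transcript_id "C01"; biotype "novel";
chr1	lncage	exon	1001	1400	.	+	.	gene_id "XG01"; transcript_id "C01"; biotype "novel";
chr1	lncage	exon	1601	2200	.	+	.	gene_id "XG01"; transcript_id "C01"; biotype "novel";
chr1	lncage	transcript	10001	12400	.	-	.	gene_id "XG02"; transcript_id "C02"; biotype "novel";
chr1	lncage	exon	10001	10400	.	-	.	gene_id "XG02"; transcript_id "C02"; biotype "novel";
chr1	lncage	exon	10901	11300	.	-	.	gene_id "XG02"; transcript_id "C02"; biotype "novel";
chr1	lncage	exon	11801	12400	.	-	.	gene_id "XG02"; transcript_id "C02"; biotype "novel";
chr1	lncage	transcript	20001	21500	.	+	.	gene_id "XG03"; transcript_id "C03"; biotype "novel";
chr1	lncage	exon	20001	21500	.	+	.	gene_id "XG03"; transcript_id "C03"; biotype "novel";
chr1	lncage	transcript	30001	30600	.	+	.	gene_id "XG04"; transcript_id "C04"; biotype "novel";
chr1	lncage	exon	30001	30600	.	+	.	gene_id "XG04"; transcript_id "C04"; biotype "novel";
chr1	lncage	transcript	40001	40700	.	-	.	gene_id "XG05"; transcript_id "C05"; biotype "novel";
chr1	lncage	exon	40001	40700	.	-	.	gene_id "XG05"; transcript_id "C05"; biotype "novel";
chr1	lncage	transcript	1001	1800	.	+	.	gene_id "XG06"; transcript_id "C06"; biotype "novel";
chr1	lncage	exon	1001	1800	.	+	.	gene_id "XG06"; transcript_id "C06"; biotype "novel";
chr1	lncage	transcript	10001	10600	.	-	.	gene_id "XG07"; transcript_id "C07"; biotype "novel";
chr1	lncage	exon	10001	10600	.	-	.	gene_id "XG07"; transcript_id "C07"; biotype "novel";
chr1	lncage	transcript	20500	20900	.	+	.	gene_id "XG08"; transcript_id "C08"; biotype "novel";
chr1	lncage	exon	20500	20900	.	+	.	gene_id "XG08"; transcript_id "C08"; biotype "novel";
chr1	lncage	transcript	11801	12600	.	-	.	gene_id "XG09"; transcript_id "C09"; biotype "novel";
chr1	lncage	exon	11801	12600	.	-	.	gene_id "XG09"; transcript_id "C09"; biotype "novel";
chr1	lncage	transcript	50001	50149	.	+	.	gene_id "XG10"; transcript_id "C10"; biotype "novel";
chr1	lncage	exon	50001	50149	.	+	.	gene_id "XG10"; transcript_id "C10"; biotype "novel";
chr1	lncage	transcript	50501	50640	.	-	.	gene_id "XG11"; transcript_id "C11"; biotype "novel";
chr1	lncage	exon	50501	50640	.	-	.	gene_id "XG11"; transcript_id "C11"; biotype "novel";
chr1	lncage	transcript	51001	51500	.	+	.	gene_id "XG12"; transcript_id "C12"; biotype "novel";
chr1	lncage	exon	51001	51500	.	+	.	gene_id "XG12"; transcript_id "C12"; biotype "novel";
chr1	lncage	transcript	52001	52600	.	-	.	gene_id "XG13"; transcript_id "C13"; biotype "novel";
chr1	lncage	exon	52001	52600	.	-	.	gene_id "XG13"; transcript_id "C13"; biotype "novel";
chr1	lncage	transcript	55001	55600	.	+	.	gene_id "XG14"; transcript_id "C14"; biotype "novel";
chr1	lncage	exon	55001	55600	.	+	.	gene_id "XG14"; transcript_id "C14"; biotype "novel";
chr1	lncage	transcript	53001	53800	.	+	.	gene_id "XG15"; transcript_id "C15"; biotype "novel";
chr1	lncage	exon	53001	53800	.	+	.	gene_id "XG15"; transcript_id "C15"; biotype "novel";
chr1	lncage	transcript	1101	1700	.	-	.	gene_id "XG16"; transcript_id "C16"; biotype "novel";
chr1	lncage	exon	1101	1700	.	-	.	gene_id "XG16"; transcript_id "C16"; biotype "novel";
chr1	lncage	transcript	20601	21100	.	-	.	gene_id "XG17"; transcript_id "C17"; biotype "novel";
chr1	lncage	exon	20601	21100	.	-	.	gene_id "XG17"; transcript_id "C17"; biotype "novel";
chr1	lncage	transcript	10451	10850	.	+	.	gene_id "XG18"; transcript_id "C18"; biotype "novel";
chr1	lncage	exon	10451	10850	.	+	.	gene_id "XG18"; transcript_id "C18"; biotype "novel";
chr1	lncage	transcript	11351	11750	.	-	.	gene_id "XG19"; transcript_id "C19"; biotype "novel";
chr1	lncage	exon	11351	11750	.	-	.	gene_id "XG19"; transcript_id "C19"; biotype "novel";
chr1	lncage	transcript	54001	54400	.	-	.	gene_id "XG20"; transcript_id "C20"; biotype "novel";
chr1	lncage	exon	54001	54400	.	-	.	gene_id "XG20"; transcript_id "C20"; biotype "novel";
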