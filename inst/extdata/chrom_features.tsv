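chrom	length_mb	exon_count	coding_gene_count
chr1	249.25	19229	2058
chr2	243.20	14611	1309
chr3	198.02	11557	1078
chr4	191.15	8337	752
chr5	180.92	9427	876
chr6	171.12	10134	1048
chr7	159.14	9712	989
chr8	146.36	7119	677
chr9	141.21	8004	786
chr10	135.53	8204	733
chr11	135.01	10598	1298
chr12	133.85	11080	1034
chr13	115.17	3617	327
chr14	107.35	6920	830
chr15	102.53	6869	613
chr16	90.35	8933	873
chr17	81.20	11166	1197
chr18	78.08	3210	270
chr19	59.13	10559	1472
chr20	63.03	5224	544
chr21	48.13	2164	234
chr22	51.30	4519	488
chrX	155.27	7206	842
chrY	59.37	684	71
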