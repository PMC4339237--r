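id	annotation	gene	feature	chrom	start	end
t1	ensembl	LUZP6	transcript_span	7	135612022	135612198
t2	ensembl	PIGY	transcript_span	4	89442724	89442940
t3	ensembl	PIK3CA	final_exon	3	178951882	178957881
t4	refgene	PIK3CA	final_exon	3	178951882	178952497
.	ensembl	MTPN	gene_span	7	135611509	135662101
.	refgene	MTPN	gene_span	7	135611503	135662204
.	refgene	LUZP6	gene_span	7	135611503	135662204
.	ensembl	PECAM1	gene_span	HG183_PATCH	62399863	62491136
.	refgene	PECAM1	gene_span	17	62396777	62407083
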