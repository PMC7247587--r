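locus_id	chrom	start	end	strand	n_exons	exonic_length_bp	fpkm_mean	fpkm_high	fpkm_low	log2fc	p	q
MSTRG.4390	14	518688	534106	-	2	20919	2.586	2.672	2.507	0.0661	0.501	0.796
MSTRG.4802	14	67986656	67991285	-	5	806	1.009	0.798	1.205	-0.6310	0.004	0.091
MSTRG.5042	15	27503347	27512980	+	7	3002	0.843	1.044	0.658	0.6330	0.043	0.287
MSTRG.7472	18	39037005	39043726	+	7	1920	11.200	11.016	11.370	-0.1053	0.886	0.966
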