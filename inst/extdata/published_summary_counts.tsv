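quantity	value
n_high_group	12
n_low_group	13
de_loci_total	745
de_loci_lncRNA	219
network_edges_total	16709
network_edges_positive	15783
cis_interactions_total	45
hub_lncRNAs_with_cis_partner	18
rif_significance_level	0.05
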