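Published summary values from a bovine liver feed-efficiency lncRNA study
(25 bulls: 12 high- and 13 low-efficiency after outlier exclusion), used by
the package's consistency checks and by scripts/acceptance.R:

hub_lncrna_summary.tsv       positional/structural/expression characteristics
                             of four hub lncRNAs as printed (FPKM group means,
                             overall mean, DE statistics)
published_summary_counts.tsv printed whole-study counts (DE loci, network
                             edge totals and signs, cis-interaction counts)
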