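# Published per-chromosome OR repertoire counts for Chinese perch:
# functional genes, pseudogenes and genomic cluster counts per linkage
# group, with unplaced scaffold genes pooled under LGUN.
contig	n_functional	n_pseudo	n_clusters
LG4	8	2	1
LG6	1	0	1
LG9	37	12	2
LG19	40	4	2
LG22	33	2	2
LGUN	4	9	NA
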