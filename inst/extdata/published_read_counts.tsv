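group	site	paired_trimmed_reads
treated	gills	1710396
treated	eye	4427528
treated	skin	2560417
treated	all	8698341
control	gills	2385590
control	eye	6568250
control	skin	2570958
control	all	11524798
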