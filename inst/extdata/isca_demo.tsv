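chrom	start	end	classification	frequency	dosage_type	source
chr1	146105170	147844758	pathogenic		loss	demo-isca-synthetic
chr7	72643631	74142190	pathogenic		gain	demo-isca-synthetic
chr15	22770421	28823721	pathogenic		loss	demo-isca-synthetic
chr17	14098660	15501133	pathogenic		gain	demo-isca-synthetic
chr16	29674985	30199927	pathogenic		loss	demo-isca-synthetic
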