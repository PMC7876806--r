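region	chrom	start_pos	end_pos	n_cpgs	n_dmr_cpgs
1	chr1	1	701	15	0
2	chr1	10701	11401	15	0
3	chr1	21401	22101	15	12
4	chr1	32101	32801	15	0
5	chr1	42801	43401	13	0
6	chr1	53401	54051	14	0
7	chr1	64051	64501	10	0
8	chr1	74501	75151	14	2
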