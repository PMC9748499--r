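transcript_id	snp_id	replicate_id	tissue	genotype_sampled	total_reads	distal_reads
AT1G01010	AT1G01010_s1	R1	scion	Col-0	842	6
AT1G01010	AT1G01010_s1	R2	scion	Col-0	911	9
AT1G01010	AT1G01010_s1	R3	scion	Col-0	780	7
AT1G01010	AT1G01010_s2	R1	scion	Col-0	1204	13
AT1G01010	AT1G01010_s2	R2	scion	Col-0	1100	10
AT1G01010	AT1G01010_s2	R3	scion	Col-0	1333	15
AT2G21330	AT2G21330_s1	R1	scion	Col-0	450	41
AT2G21330	AT2G21330_s1	R2	scion	Col-0	505	52
AT2G21330	AT2G21330_s1	R3	scion	Col-0	462	47
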