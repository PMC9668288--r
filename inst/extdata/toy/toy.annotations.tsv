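chrom	pos	ref	alt	gene	consequence	maf_internal	maf_external	revel_score	mtr_percentile	ext_observed	fs	mq	qual	rprs	mqrs	filter_status	ext_coverage_frac	ext_z	ext_mq	ext_pass_frac	ccds
1	101	A	G	G1	stop_gained	0.001	0.001	NA	NA	TRUE	5	60	3000	0	0	PASS	0.95	0.5	60	0.99	TRUE
1	102	A	G	G1	stop_gained	0.001	0.001	NA	NA	TRUE	5	60	3000	0	0	PASS	0.95	0.5	60	0.99	TRUE
1	103	A	G	G1	missense_variant	0.001	0.001	0.7	30	TRUE	5	60	3000	0	0	PASS	0.95	0.5	60	0.99	TRUE
1	104	A	G	G1	missense_variant	0.001	0.001	0.7	30	TRUE	5	60	3000	0	0	PASS	0.95	0.5	60	0.99	TRUE
1	105	A	G	G1	synonymous_variant	0.001	0.001	NA	NA	TRUE	5	60	3000	0	0	PASS	0.95	0.5	60	0.99	TRUE
1	106	A	G	G1	synonymous_variant	0.001	0.001	NA	NA	TRUE	5	60	3000	0	0	PASS	0.95	0.5	60	0.99	TRUE
X	201	A	G	GX	stop_gained	0.001	0.001	NA	NA	TRUE	5	60	3000	0	0	PASS	0.95	0.5	60	0.99	TRUE
X	202	A	G	GX	stop_gained	0.001	0.001	NA	NA	TRUE	5	60	3000	0	0	PASS	0.95	0.5	60	0.99	TRUE
X	203	A	G	GX	missense_variant	0.001	0.001	0.7	30	TRUE	5	60	3000	0	0	PASS	0.95	0.5	60	0.99	TRUE
X	204	A	G	GX	missense_variant	0.001	0.001	0.7	30	TRUE	5	60	3000	0	0	PASS	0.95	0.5	60	0.99	TRUE
X	205	A	G	GX	synonymous_variant	0.001	0.001	NA	NA	TRUE	5	60	3000	0	0	PASS	0.95	0.5	60	0.99	TRUE
X	206	A	G	GX	synonymous_variant	0.001	0.001	NA	NA	TRUE	5	60	3000	0	0	PASS	0.95	0.5	60	0.99	TRUE
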