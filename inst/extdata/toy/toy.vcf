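##fileformat=VCFv4.2
##source=rvburden
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S01	S02	S03	S04	S05	S06	S07	S08	S09	S10	S11	S12	S13	S14	S15	S16	S17	S18	S19	S20
1	101	1-101-A-G	A	G	3000	PASS	.	GT:DP:GQ:AD	0/1:100:99:50,50	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/1:100:99:50,50	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0
1	102	1-102-A-G	A	G	3000	PASS	.	GT:DP:GQ:AD	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/1:100:99:50,50	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0
1	103	1-103-A-G	A	G	3000	PASS	.	GT:DP:GQ:AD	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	1/1:100:99:2,98	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0
1	104	1-104-A-G	A	G	3000	PASS	.	GT:DP:GQ:AD	0/0:100:99:100,0	0/1:100:99:50,50	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0
1	105	1-105-A-G	A	G	3000	PASS	.	GT:DP:GQ:AD	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/1:100:99:50,50	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0
1	106	1-106-A-G	A	G	3000	PASS	.	GT:DP:GQ:AD	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0
X	201	X-201-A-G	A	G	3000	PASS	.	GT:DP:GQ:AD	0:100:99:100,0	0:100:99:100,0	1:100:99:2,98	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/1:100:99:50,50	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0
X	202	X-202-A-G	A	G	3000	PASS	.	GT:DP:GQ:AD	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/1:100:99:50,50	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0
X	203	X-203-A-G	A	G	3000	PASS	.	GT:DP:GQ:AD	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	1:100:99:2,98	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/1:100:99:50,50	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0
X	204	X-204-A-G	A	G	3000	PASS	.	GT:DP:GQ:AD	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0
X	205	X-205-A-G	A	G	3000	PASS	.	GT:DP:GQ:AD	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	1:100:99:2,98	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0
X	206	X-206-A-G	A	G	3000	PASS	.	GT:DP:GQ:AD	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0	0/0:100:99:100,0
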