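##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	NA001	NA002	NA003	NA004	NA005	NA006	NA007	NA008	NA009	NA010	NA011	NA012	NA013	NA014	NA015	NA016	NA017	NA018	NA019	NA020	NA021	NA022	NA023	NA024	NA025	NA026	NA027	NA028	NA029	NA030	NA031	NA032	NA033	NA034	NA035	NA036	NA037	NA038	NA039	NA040
1	1000	rs101	A	G	.	PASS	.	GT	0/1	0/1	0/1	0/0	1/1	0/0	0/1	0/0	0/0	0/1	1/1	0/1	1/1	0/0	0/0	1/1	0/1	0/0	0/0	0/1	0/1	0/1	0/0	0/0	1/1	0/1	0/0	1/1	0/1	0/0	0/0	1/1	0/0	0/0	1/1	0/0	0/0	0/1	0/1	0/1
1	2000	rs102	A	G	.	PASS	.	GT	1/1	0/1	1/1	1/1	1/1	0/0	0/1	0/1	1/1	0/1	1/1	0/1	0/1	1/1	1/1	1/1	0/0	1/1	0/0	1/1	1/1	0/1	0/1	0/0	0/1	0/1	0/1	1/1	0/1	1/1	1/1	1/1	1/1	0/1	0/0	0/1	0/1	0/1	1/1	1/1
1	3000	rs103	A	G	.	PASS	.	GT	0/1	0/0	./.	0/1	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/1	0/0	1/1	1/1	./.	0/1	0/1	0/0	0/1	0/0	0/0	0/0	1/1	0/1	0/1	0/0	0/0	0/0	0/1	0/0	0/1	0/0	0/0	0/1	0/1	0/0	0/1	0/1
1	4000	rs104	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
1	5000	rs105	A	G	.	PASS	.	GT	0/0	0/1	0/1	0/1	0/0	1/1	0/0	0/0	0/0	0/0	0/1	0/1	0/1	0/1	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/1	0/0	0/0	0/1	0/1	0/1	0/1	0/1	0/0
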