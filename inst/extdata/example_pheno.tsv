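sample	disease	biomarker
NA001	1	4.906
NA002	0	3.497
NA003	1	5.946
NA004	1	6.057
NA005	1	6.29
NA006	0	6.565
NA007	1	5.507
NA008	0	4.922
NA009	0	3.978
NA010	1	6.792
NA011	1	6.226
NA012	1	6.479
NA013	0	4.154
NA014	1	6.978
NA015	1	5.613
NA016	1	6.239
NA017	0	5.423
NA018	1	4.881
NA019	0	4.334
NA020	1	4.496
NA021	1	6.651
NA022	0	2.879
NA023	0	6.586
NA024	0	4.984
NA025	1	7.124
NA026	0	4.837
NA027	1	6.591
NA028	0	4.358
NA029	1	3.038
NA030	1	5.821
NA031	1	5.78
NA032	1	6.151
NA033	1	5.106
NA034	1	4.004
NA035	0	4.85
NA036	0	7.562
NA037	1	5.194
NA038	0	4.454
NA039	1	4.967
NA040	1	6.394
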