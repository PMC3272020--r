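sample_id	Bacteroides	Prevotella	Faecalibacterium	Roseburia	Alistipes
sample001	69	34	35	5	7
sample002	63	35	32	3	17
sample003	79	19	30	12	10
sample004	40	55	22	28	5
sample005	78	51	13	4	4
sample006	38	42	49	14	7
sample007	59	49	26	12	4
sample008	57	37	27	8	21
sample009	58	16	42	16	18
sample010	55	35	43	8	9
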