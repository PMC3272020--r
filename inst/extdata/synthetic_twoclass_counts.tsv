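sample_id	taxon1	taxon2	taxon3	taxon4	taxon5	taxon6	taxon7	taxon8
A01	103	62	72	11	18	10	19	5
A02	90	95	77	8	15	11	0	4
A03	128	70	36	30	21	9	2	4
A04	83	107	58	16	12	7	11	6
A05	99	64	91	5	15	10	10	6
A06	131	41	71	20	20	6	7	4
A07	71	87	64	4	37	6	28	3
A08	124	71	46	15	6	21	17	0
A09	67	80	93	8	31	3	9	9
A10	100	80	79	9	9	6	13	4
A11	95	118	43	17	2	5	16	4
A12	134	68	49	13	5	18	4	9
B01	14	0	12	32	6	68	85	83
B02	4	3	8	14	5	58	52	156
B03	1	6	19	7	24	37	80	126
B04	11	4	17	5	5	35	83	140
B05	35	2	8	13	21	67	48	106
B06	10	12	28	0	11	47	97	95
B07	47	2	3	2	20	58	70	98
B08	22	5	18	22	8	65	39	121
B09	10	2	27	16	32	41	87	85
B10	4	0	7	16	12	35	82	144
B11	12	0	5	22	4	70	48	139
B12	13	11	4	19	33	74	38	108
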