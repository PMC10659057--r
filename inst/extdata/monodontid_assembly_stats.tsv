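assembly	species	total_length_mbp	n_contigs	n_scaffolds	gap_pct	max_contig_mbp	max_scaffold_mbp	contig_l50	scaffold_l50	contig_n50_mbp	scaffold_n50_mbp
Dl_Jones_	Delphinapterus_leucas	2363	29098	5906	1.518	1.711	120.97	3611	21	0.197	31.183
Dl_zoo_	Delphinapterus_leucas	2357	35102	6972	1.264	1.083	182.318	4473	9	0.159	107.97
Dl_3_	Delphinapterus_leucas	2404	20104	9110	0.056	2.386	135.447	2190	12	0.316	88.022
Dl_4_	Delphinapterus_leucas	2397	12979	5851	0.038	3.224	135.399	1249	12	0.551	87.682
Dl_5_	Delphinapterus_leucas	2379	10046	4370	0.032	5.618	134.683	1035	12	0.657	87.683
Mm_West_	Monodon_monoceros	2351	813468	21006	8.259	0.135	7.088	63731	464	0.010	1.483
Mm_Damas_	Monodon_monoceros	2342	414	101	0.001	83.581	182.209	36	9	22.031	108.564
Mm_3_	Monodon_monoceros	2337	9252	6465	0.035	5.696	131.705	861	12	0.708	83.77
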