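assembly	species	reference	debris	translocation	inversion	relocation	unassessed	congruent
Dl_Jones_	Delphinapterus_leucas	Dl_5_	7096636	31779574	29465224	18044276	109570873	2166825960
Dl_zoo_	Delphinapterus_leucas	Dl_5_	11212633	14447594	23928201	1165563	116520692	2189291240
Dl_3_	Delphinapterus_leucas	Dl_5_	13985070	4419089	43013607	1546419	274690520	2068226002
Dl_4_	Delphinapterus_leucas	Dl_5_	10800991	1403102	40843164	1899502	191862255	2122477807
Mm_Damas_	Monodon_monoceros	Mm_3_	59103779	909121	124283977	7848688	115575344	2034233699
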