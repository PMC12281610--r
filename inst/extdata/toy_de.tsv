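gene_id	log2fc	fdr
g1	8.0	0.02
g2	8.4	0.01
g3	9.1	0.001
g4	10.0	0.06
g5	-2.0	0.5
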