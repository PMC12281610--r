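##gff-version 3
chr	toy	gene	241	400	.	+	.	ID=g1
chr	toy	gene	451	560	.	-	.	ID=g2
chr	toy	gene	621	760	.	+	.	ID=g3
chr	toy	gene	821	940	.	+	.	locus_tag=g4
chr	toy	gene	941	990	.	+	.	ID=g5
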