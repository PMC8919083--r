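name	symbol	uniprot	pts1	localisation
Acyl-CoA oxidase 1	Acox1	F1R071_DANRE	SKL	PO
Acyl-CoA oxidase 3	Acox3	F1QXK3_DANRE	AKL	PO
Acyl-CoA oxidase-like	Acoxl	F1R4J4_DANRE	-	PO?
L-alpha-hydroxyacid oxidase 1	Hao1	Q7SXE5_DANRE	SRI	PO
L-alpha-hydroxyacid oxidase 2	Hao2	F1QCD8_DANRE	SRL	PO
D-amino-acid oxidase 1	Dao1	Q4V981_DANRE	SRL	PO
D-amino-acid oxidase 2	Dao2	Q6NY97_DANRE	SRL	PO
D-amino-acid oxidase 3	Dao3	Q6P009_DANRE	SRL	PO
D-aspartate oxidase	Ddo	A0A0R4IZE6_DANRE	ARL	PO
L-pipecolic acid oxidase	Pipox	A7MBQ2_DANRE	SSL	PO
Polyamine oxidase	Paox	B8JJQ4_DANRE	SKL	PO
Urate oxidase	Uox	Q6DG85_DANRE	ARM	PO
Xanthine oxidase	Xdh	A0A2R8Q1T4_DANRE	-	Cyt
L-gulonolactone oxidase	Gulo	-	-	absent
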