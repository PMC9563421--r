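compound	MRPs A	MRPs B	MRPs C	MRPs D	MRPs E	flavor
(E)-2-Octenal	9	9	27	9	9	fatty; plastic
Octanal	3	9	9	9	27	fatty
(E)-2-Decenal	1	3	9	3	3	fatty; green; waxy
(E,E)-2,4-Nonadienal	9	9	9	9	3	fatty; green; waxy
(E)-2-Undecenal	1	3	3	3	3	fatty; green; waxy
2-Pentylfuran	9	3	9	3	3	fatty; fruity; green
1-Octanol	1	3	3	3	3	fatty; floral; green
Decanal	3	3	3	9	9	fatty; floral; green
(E)-2-Octen-1-ol	3	9	27	9	3	sour; fatty; gravy
3-(Methylthio)propanal	3	9	3	9	3	boiled potato
n-Decanoic acid	3	3	3	3	3	rubber; sour
(E,E)-2,4-Decadienal	9	27	9	9	9	bedbug
Butanoic acid	ND	ND	1	1	1	rancid; moldy
Octanoic acid	9	3	9	9	9	rancid; fermented
(E,E)-3,5-Octadien-2-one	3	9	9	9	9	rancid
Phenol	9	9	9	9	9	plastic; rancid
1-Octen-3-ol	3	9	9	3	3	moldy
Trimethyl-pyrazine	ND	ND	9	9	9	moldy; plastic
Nonanoic acid	9	3	9	9	9	moldy; rancid
2-Ethyl-6-methylpyrazine	1	1	3	3	3	peanut; roasted
Ethyl myristate	9	3	3	3	3	peanut; rubber
Hexanoic acid	1	1	1	1	1	rancid; bitter
2-Ethyl-3,5-dimethylpyrazine	81	81	243	243	243	peanut; roasted
Hexanal	1	1	1	1	1	green
p-Cresol	ND	ND	1	9	3	herbal medicine
(E)-2-Nonenal	27	27	27	27	27	fatty; mushroom
Heptanal	9	9	27	27	27	citrus-like
Heptanoic acid	1	1	1	1	1	sweaty
Benzene acetaldehyde	27	27	27	27	27	stale; floral
Nonanal	9	9	27	9	27	citrus-like; fatty
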