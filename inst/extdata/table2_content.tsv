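compound	MRPs A	MRPs B	MRPs C	MRPs D	MRPs E	ions
(E)-2-Octenal	2.16 ± 0.42	4.47 ± 0.24	6.38 ± 0.05	3.45 ± 0.15	4.64 ± 0.62	41, 55, 70
Octanal	0.82 ± 0.02	1.37 ± 0.28	1.76 ± 0.07	1.74 ± 0.33	2.35 ± 0.20	41, 57, 84
(E)-2-Decenal	0.72 ± 0.04	1.58 ± 0.03	1.62 ± 0.19	1.49 ± 0.05	1.48 ± 0.02	41, 70, 55
(E,E)-2,4-Nonadienal	0.38 ± 0.03	1.17 ± 0.12	0.51 ± 0.02	0.31 ± 0.04	0.12 ± 0.01	81, 41, 67
(E)-2-Undecenal	0.74 ± 0.02	1.47 ± 0.16	1.29 ± 0.05	1.49 ± 0.03	1.37 ± 0.05	41, 70, 55
2-Pentylfuran	2.73 ± 0.29	1.46 ± 0.15	3.31 ± 0.04	0.76 ± 0.08	1.84 ± 0.11	81, 53, 82
1-Octanol	0.42 ± 0.11	0.62 ± 0.04	0.72 ± 0.05	0.93 ± 0.12	0.90 ± 0.08	56, 41, 69
Decanal	0.53 ± 0.07	0.61 ± 0.02	0.36 ± 0.01	0.79 ± 0.08	0.91 ± 0.04	41, 43, 57
(E)-2-Octen-1-ol	0.75 ± 0.17	1.10 ± 0.05	2.55 ± 0.02	1.19 ± 0.11	0.84 ± 0.03	41, 55, 83
3-(Methylthio)propanal	0.24 ± 0.02	0.76 ± 0.03	0.34 ± 0.03	0.84 ± 0.05	1.25 ± 0.09	48, 104, 76
n-Decanoic acid	0.44 ± 0.01	0.50 ± 0.06	0.30 ± 0.01	0.59 ± 0.03	0.64 ± 0.03	60, 73, 55
(E,E)-2,4-Decadienal	2.25 ± 0.30	5.23 ± 0.98	2.95 ± 0.01	2.44 ± 0.28	1.25 ± 0.05	81, 41, 67
Butanoic acid	0.00 ± 0.00	0.00 ± 0.00	0.08 ± 0.00	0.80 ± 0.13	0.05 ± 0.01	60, 73, 39
Octanoic acid	0.23 ± 0.03	0.15 ± 0.01	0.37 ± 0.02	0.40 ± 0.04	0.40 ± 0.10	60, 73, 43
(E,E)-3,5-Octadien-2-one	0.38 ± 0.07	0.53 ± 0.05	1.84 ± 0.13	0.74 ± 0.05	0.84 ± 0.19	55, 43, 125
Phenol	0.24 ± 0.08	0.18 ± 0.03	0.11 ± 0.01	0.16 ± 0.01	0.17 ± 0.02	68, 40, 55
1-Octen-3-ol	1.94 ± 0.53	4.34 ± 0.65	3.94 ± 0.09	1.69 ± 0.35	2.48 ± 0.20	56, 41, 59
Trimethyl-pyrazine	0.00 ± 0.00	0.00 ± 0.00	0.48 ± 0.03	0.48 ± 0.07	0.72 ± 0.07	121, 67, 80
Nonanoic acid	0.32 ± 0.03	0.17 ± 0.01	0.40 ± 0.07	0.40 ± 0.03	0.52 ± 0.03	60, 73, 41
2-Ethyl-6-methylpyrazine	0.16 ± 0.01	0.16 ± 0.02	0.94 ± 0.09	1.00 ± 0.12	1.28 ± 0.20	42, 108, 39
Ethyl myristate	2.20 ± 0.36	1.30 ± 0.33	0.98 ± 0.02	1.19 ± 0.15	1.13 ± 0.13	77, 106, 51
Hexanoic acid	0.46 ± 0.17	2.56 ± 0.05	2.24 ± 0.07	2.89 ± 0.17	1.56 ± 0.17	60, 73, 41
2-Ethyl-3,5-dimethylpyrazine	0.59 ± 0.03	0.50 ± 0.03	1.12 ± 0.03	0.87 ± 0.32	0.85 ± 0.07	135, 56, 39
Hexanal	0.45 ± 0.09	0.36 ± 0.01	0.38 ± 0.02	0.31 ± 0.01	0.51 ± 0.03	44, 56, 41
p-Cresol	0.00 ± 0.00	0.00 ± 0.00	0.00 ± 0.00	0.67 ± 0.03	0.28 ± 0.02	43, 57, 128
(E)-2-Nonenal	0.68 ± 0.10	1.66 ± 0.22	1.31 ± 0.15	2.97 ± 0.32	1.19 ± 0.03	41, 55, 70
Heptanal	0.57 ± 0.08	0.57 ± 0.07	1.38 ± 0.04	1.44 ± 0.45	1.84 ± 0.17	70, 55, 44
Heptanoic acid	0.06 ± 0.00	0.06 ± 0.00	0.07 ± 0.02	0.07 ± 0.02	0.11 ± 0.01	60, 73, 87
Benzene acetaldehyde	5.57 ± 0.87	2.97 ± 0.83	1.83 ± 0.07	5.62 ± 1.33	4.09 ± 0.87	91, 120, 65
Nonanal	4.95 ± 0.93	4.65 ± 0.75	8.37 ± 0.24	4.49 ± 0.21	6.90 ± 0.69	41, 57, 70
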