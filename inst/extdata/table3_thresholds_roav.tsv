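compound	class	ri	threshold_ugkg	MRPs A	MRPs B	MRPs C	MRPs D	MRPs E
(E,E)-3,5-Octadien-2-one	ketone	1068	0.1	0.007	0.010	0.016	0.009	0.010
Hexanal	aldehyde	1087	0.0011	0.687	0.644	0.309	0.32	0.548
Heptanal	aldehyde	1182	0.0009	1.066	1.252	1.369	1.848	2.394
2-Pentylfuran	furan	1235	0.019	0.244	0.153	0.156	0.046	0.113
p-Cresol	phenol	1251	0.0084	0	0	0	0.092	0.039
Octanal	aldehyde	1291	0.0004	3.48	6.801	3.929	5.023	6.876
Ethyl myristate	ester	1322	0.18	0.021	0.014	0.005	0.008	0.007
2-Ethyl-3,5-dimethylpyrazine	pyrazine	1346	0.00001	100	100	100	100	100
2-Ethyl-6-methylpyrazine	pyrazine	1371	0.04	0.007	0.008	0.021	0.029	0.037
Nonanal	aldehyde	1395	0.0026	3.234	3.545	2.874	1.992	3.113
Trimethyl-pyrazine	pyrazine	1402	0.033	0	0	0.013	0.017	0.026
(E)-2-Octenal	aldehyde	1426	0.0027	1.359	3.286	2.11	1.475	2.013
1-Octen-3-ol	alcohol	1438	0.0027	1.222	3.191	1.303	0.723	1.076
3-(Methylthio)propanal	aldehyde	1454	0.0014	0.298	1.083	0.214	0.69	1.047
Decanal	aldehyde	1497	0.0026	0.352	0.466	0.124	0.35	0.409
(E)-2-Nonenal	aldehyde	1531	0.00009	12.884	36.53	12.996	38.106	15.54
(E)-2-Octen-1-ol	alcohol	1544	0.04	0.032	0.055	0.057	0.034	0.025
1-Octanol	alcohol	1559	0.022	0.032	0.056	0.029	0.049	0.048
Butanoic acid	acid	1631	0.004	0	0	0.017	0.23	0.015
Benzene acetaldehyde	aldehyde	1643	0.0017	5.564	3.462	0.96	3.818	2.818
(E)-2-Decenal	aldehyde	1654	0.0027	0.457	1.162	0.536	0.636	0.644
(E,E)-2,4-Nonadienal	aldehyde	1778	0.0002	3.285	11.567	2.277	1.807	0.686
(E)-2-Undecenal	aldehyde	1861	0.044	0.029	0.066	0.026	0.039	0.036
(E,E)-2,4-Decadienal	aldehyde	2001	0.0023	1.665	4.514	1.145	1.227	0.638
Phenol	phenol	2020	0.046	0.009	0.008	0.002	0.004	0.004
Hexanoic acid	acid	2050	0.04	0.02	0.127	0.05	0.083	0.046
Heptanoic acid	acid	2130	0.022	0.005	0.006	0.003	0.004	0.006
Octanoic acid	acid	2264	0.0051	0.077	0.058	0.065	0.091	0.092
n-Decanoic acid	acid	2276	0.05	0.015	0.02	0.005	0.014	0.015
Nonanoic acid	acid	2370	0.02	0.027	0.017	0.018	0.023	0.031
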