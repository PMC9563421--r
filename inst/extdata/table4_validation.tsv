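compound	actual	pred_pcf	pred_csi	pred_cpm	err_pcf	err_csi	err_cpm
(E)-2-Octenal	1.682	2.263	1.895	1.638	0.581	0.213	0.044
Octanal	3.972	5.361	3.971	3.972	1.389	0.001	0
(E,E)-2,4-Nonadienal	1.032	4.265	-21.173	0.971	3.233	22.205	0.061
(E,E)-2,4-Decadienal	0.843	1.966	-6.910	0.803	1.123	7.753	0.040
1-Octen-3-ol	0.826	1.568	-3.742	0.791	0.742	4.568	0.035
(E)-2-Nonenal	20.535	28.317	-45.821	22.492	7.782	66.356	1.957
Heptanal	1.576	1.646	1.394	1.575	0.070	0.182	0.001
Benzene acetaldehyde	1.994	2.254	0.042	2.061	0.260	1.952	0.067
Nonanal	2.295	2.722	1.421	2.344	0.427	0.874	0.049
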