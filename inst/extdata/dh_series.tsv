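time_h	dh	sd
0	0.00	0.00
2	9.40	0.24
4	11.93	0.13
6	14.32	0.21
8	14.77	0.46
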