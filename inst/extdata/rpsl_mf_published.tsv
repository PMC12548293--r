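class	wt_control	wt_kbro3	msh2ko_control	msh2ko_kbro3
BS total	0.37	1.0	4.82	4.22
G:C>A:T	0.30	0.53	2.64	2.39
A:T>G:C	-	0.18	0.94	1.51
G:C>T:A	0.04	0.29	0.37	0.21
G:C>C:G	-	-	0.16	0.11
A:T>T:A	0.03	-	0.22	-
A:T>C:G	-	-	0.49	-
Indel total	2.0	2.32	24.79	54.97
1-indel	0.71	1.38	1.18	0.81
1-indel_(A)n	0.06	0.11	22.82	52.69
2-indel_(A)n	-	-	0.21	-
>2bp_indel	1.23	0.83	0.58	1.47
other	-	0.07	-	-
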