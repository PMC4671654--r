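sample	mean_lr	cn_printed	dlrs	species	affected
Baboon1	-1.97	0	0.97	Papio anubis	no
Rhesus1	-1.67	0	1.11	Macaca mulatta	no
Rhesus2	-1.79	0	1.14	Macaca mulatta	no
Orangutan1	-0.54	2	0.54	Pongo abelii	no
Chimp1	-0.66	2	0.31	Pan troglodytes	no
Chimp2	-0.60	2	0.32	Pan troglodytes	no
Chimp3	-0.51	2	0.29	Pan troglodytes	no
Chimp4	-0.67	2	0.28	Pan troglodytes	no
Chimp5	-0.66	2	0.29	Pan troglodytes	no
Chimp6	-0.67	2	0.32	Pan troglodytes	no
Chimp7	-0.67	2	0.33	Pan troglodytes	no
Gorilla1	-0.07	4	0.34	Gorilla gorilla	no
Gorilla2	-0.18	4	0.42	Gorilla gorilla	no
Gorilla3	-0.14	4	0.42	Gorilla gorilla	no
NA18517	0.33	5	0.12	Homo sapiens	no
NA18555	-0.32	3	0.13	Homo sapiens	no
NA15510	0.06	4	0.11	Homo sapiens	no
NA12878	-0.78	2	0.13	Homo sapiens	no
NA07535	0.04	4	0.11	Homo sapiens	no
NA18994	0.04	4	0.12	Homo sapiens	no
NA10860	0.00	4	0.10	Homo sapiens	no
MCF7	-0.30	3	0.12	Homo sapiens	no
H1-P22	-0.18	3	0.14	Homo sapiens	no
H1-P208	-0.22	3	0.10	Homo sapiens	no
PT1	-0.76	2	0.10	Homo sapiens	yes
PT2	-0.74	2	0.11	Homo sapiens	yes
PT3	-0.79	2	0.11	Homo sapiens	yes
PT4	0.02	4	0.11	Homo sapiens	yes
PT5	-0.73	2	0.15	Homo sapiens	yes
PT6	-0.78	2	0.10	Homo sapiens	yes
PT7	-0.65	2	0.31	Homo sapiens	yes
PT8	-0.77	2	0.12	Homo sapiens	yes
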