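sample_id	sex	age	status	quant
S01	male	41	1	0.214
S02	male	42	0	0.4797
S03	male	43	1	0.0878
S04	male	44	0	0.4439
S05	male	45	0	-0.3628
S06	male	46	1	0.1227
S07	male	47	0	-0.8638
S08	male	48	0	0.4896
S09	male	49	0	-0.3641
S10	male	50	0	-1.2942
S11	female	51	1	-0.7458
S12	female	52	1	0.9216
S13	female	53	0	0.7501
S14	female	54	0	-2.5086
S15	female	55	0	-3.0409
S16	female	56	1	0.0003
S17	female	57	0	-0.394
S18	female	58	0	-1.745
S19	female	59	0	0.4986
S20	female	60	0	0.271
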