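gene	model	case_carrier	control_carrier	case_noncarrier	control_noncarrier	or	p_binary	beta	se	p_quant
G1	rec	2	0	4	14	16.111111111111111	0.0789473684210527	0.728760222737104	0.913740448163652	0.4368046666242422
GX	rec	1	2	5	12	1.200000000000000	1.0000000000000000	-0.508745964686003	0.661843421893278	0.4532807793368465
G1	ptv5pcnt	2	0	4	14	16.111111111111111	0.0789473684210527	-0.661769032871078	0.881157693317497	0.4635428313223241
GX	ptv5pcnt	1	2	5	12	1.200000000000000	1.0000000000000000	-1.447162559466019	0.558337682047901	0.0196610139583394
G1	syn	0	1	6	13	0.692307692307692	0.9999999999999999	1.512855274190391	1.038028125344874	0.1643444356604450
GX	syn	0	1	6	13	0.692307692307692	0.9999999999999999	-0.316924892746962	1.079292480657711	0.7728067447210880
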