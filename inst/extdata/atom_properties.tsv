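element	mass	vdw_radius	electronegativity	covalent_radius	polarizability	ionization_energy	electron_affinity
C	12.011	1.70	2.55	0.76	1.76	11.26	1.26
N	14.007	1.55	3.04	0.71	1.10	14.53	0.00
O	15.999	1.52	3.44	0.66	0.80	13.62	1.46
S	32.06	1.80	2.58	1.05	2.90	10.36	2.08
P	30.974	1.80	2.19	1.07	3.63	10.49	0.75
SE	78.971	1.90	2.55	1.20	3.77	9.75	2.02
OTHER	40.0	1.80	2.00	1.20	3.00	8.00	0.50
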