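# RNA dinucleotide physicochemical property table (synthetic compilation).
# free_energy (kcal/mol, 37C) and enthalpy (kcal/mol) follow the Xia (1998)
# Watson-Crick nearest-neighbor parameters; entropy (cal/mol/K) is derived
# from them as (dH - dG37)/310.15 * 1000. The geometric step parameters
# (A-form helix), stacking_energy and hydrophilicity are representative
# values compiled for this package. Every property is standardized (mean 0,
# variance 1 across the 16 dinucleotides) before any encoder uses it, so
# downstream features depend only on the relative ordering of the values.
dinuc	shift	slide	rise	tilt	roll	twist	stacking_energy	entropy	enthalpy	free_energy	hydrophilicity
AA	-0.08	-1.27	3.18	-0.8	7.0	31.0	-13.7	-19.0	-6.82	-0.93	0.023
AC	0.23	-1.43	3.24	0.8	4.8	32.0	-13.8	-29.5	-11.40	-2.24	0.083
AG	-0.04	-1.50	3.30	0.5	8.5	30.0	-14.0	-27.1	-10.48	-2.08	0.035
AU	-0.06	-1.36	3.24	1.1	7.1	33.0	-15.4	-26.7	-9.38	-1.10	0.090
CA	0.11	-1.46	3.09	1.0	9.9	31.0	-14.4	-26.9	-10.44	-2.11	0.118
CC	-0.01	-1.78	3.32	0.3	8.7	32.0	-11.1	-32.7	-13.39	-3.26	0.349
CG	0.30	-1.89	3.30	-0.1	12.1	27.0	-15.6	-26.7	-10.64	-2.36	0.193
CU	0.04	-1.50	3.30	-0.5	8.5	30.0	-14.0	-27.1	-10.48	-2.08	0.378
GA	0.07	-1.70	3.38	-1.3	9.4	32.0	-14.2	-32.5	-12.44	-2.35	0.048
GC	0.07	-1.39	3.22	0.0	6.1	35.0	-16.9	-36.9	-14.88	-3.42	0.146
GG	0.01	-1.78	3.32	-0.3	8.7	32.0	-11.1	-32.7	-13.39	-3.26	0.065
GU	-0.23	-1.43	3.24	-0.8	4.8	32.0	-13.8	-29.5	-11.40	-2.24	0.160
UA	-0.02	-1.45	3.26	-0.2	10.7	32.0	-12.0	-20.5	-7.69	-1.33	0.112
UC	-0.07	-1.70	3.38	1.3	9.4	32.0	-14.2	-32.5	-12.44	-2.35	0.359
UG	-0.11	-1.46	3.09	-1.0	9.9	31.0	-14.4	-26.9	-10.44	-2.11	0.224
UU	0.08	-1.27	3.18	0.8	7.0	31.0	-13.7	-19.0	-6.82	-0.93	0.389
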