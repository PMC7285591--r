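# DNA dinucleotide physicochemical property table (synthetic compilation).
# enthalpy (kcal/mol), entropy (cal/mol/K) and free_energy (kcal/mol, 37C)
# follow the SantaLucia (1998) unified nearest-neighbor parameters; the
# geometric step parameters (shift/slide/rise in Angstrom, tilt/roll/twist
# in degrees), stacking_energy and hydrophilicity are representative values
# compiled for this package. Every property is standardized (mean 0,
# variance 1 across the 16 dinucleotides) before any encoder uses it, so
# downstream features depend only on the relative ordering of the values.
dinuc	shift	slide	rise	tilt	roll	twist	stacking_energy	entropy	enthalpy	free_energy	hydrophilicity
AA	0.06	-0.19	3.25	-1.4	0.7	35.1	-5.37	-22.2	-7.9	-1.00	0.04
AC	0.13	-0.58	3.36	-0.1	0.7	31.5	-10.51	-22.4	-8.4	-1.44	0.14
AG	0.09	-0.25	3.34	-1.7	4.5	31.9	-6.78	-21.0	-7.8	-1.28	0.08
AT	0.00	-0.59	3.31	0.0	1.1	29.3	-6.57	-20.4	-7.2	-0.88	0.14
CA	0.09	0.53	3.33	0.5	4.7	37.3	-6.57	-22.7	-8.5	-1.45	0.21
CC	0.05	-0.22	3.42	-0.1	3.6	32.9	-8.26	-19.9	-8.0	-1.84	0.49
CG	0.00	0.41	3.39	0.0	5.4	36.1	-9.69	-27.2	-10.6	-2.17	0.35
CT	-0.09	-0.25	3.34	1.7	4.5	31.9	-6.78	-21.0	-7.8	-1.28	0.52
GA	-0.03	-0.33	3.38	-1.5	1.9	36.3	-9.81	-22.2	-8.2	-1.30	0.10
GC	0.00	-0.38	3.40	0.0	0.3	33.6	-14.59	-24.4	-9.8	-2.24	0.28
GG	-0.05	-0.22	3.42	0.1	3.6	32.9	-8.26	-19.9	-8.0	-1.84	0.44
GT	-0.13	-0.58	3.36	0.1	0.7	31.5	-10.51	-22.4	-8.4	-1.44	0.17
TA	0.00	0.05	3.42	0.0	3.3	37.8	-3.82	-21.3	-7.2	-0.58	0.02
TC	0.03	-0.33	3.38	1.5	1.9	36.3	-9.81	-22.2	-8.2	-1.30	0.36
TG	-0.09	0.53	3.33	-0.5	4.7	37.3	-6.57	-22.7	-8.5	-1.45	0.24
TT	-0.06	-0.19	3.25	1.4	0.7	35.1	-5.37	-22.2	-7.9	-1.00	0.04
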