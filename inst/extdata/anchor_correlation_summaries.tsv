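gene	r_mesa	p_fdr_mesa	r_cedar	p_fdr_cedar
EVL	0.65	5.37e-140	0.86	5.52e-80
ARHGAP17	0.69	1.13e-169	0.79	9.20e-59
DNMT1	0.69	1.10e-169	0.79	1.67e-58
RAPGEF1	0.69	1.66e-168	0.76	2.09e-51
CLEC16A	0.67	3.51e-154	0.78	2.27e-55
ARHGEF18	0.67	6.61e-152	0.77	1.14e-53
SIPA1	0.64	9.91e-137	0.79	1.08e-57
GLG1	0.65	4.24e-143	0.77	2.45e-53
HNRNPUL2	0.68	7.38e-161	0.74	1.31e-47
FNBP1	0.66	1.21e-146	0.76	1.56e-51
C11ORF54	-0.47	2.07e-67	-0.53	1.18e-20
LOC100132510	-0.43	2.56e-55	-0.57	1.22e-24
HNMT	-0.44	3.96e-58	-0.58	4.75e-25
PRKAG1	-0.51	1.81e-79	-0.54	2.16e-21
TMEM120A	-0.43	1.97e-54	-0.64	2.94e-32
CHCHD1	-0.55	1.36e-93	-0.53	1.72e-20
ELMOD2	-0.53	8.30e-86	-0.56	6.61e-23
LOC100129118	-0.56	2.50e-97	-0.54	4.80e-21
TBC1D7	-0.48	1.36e-69	-0.62	7.81e-30
C2ORF76	-0.55	8.70e-94	-0.58	1.31e-25
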