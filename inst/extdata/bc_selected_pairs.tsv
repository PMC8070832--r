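# Inversely correlated female-biased gene / X-linked miRNA pairs in
# breast cancer (BC). T_* statistics: pair correlation in tumor samples;
# N_*: in matched normal samples.
mRNA	miRNA	T_CC	T_P	T_FDR	N_CC	N_P	N_FDR
GPRIN2	hsa-mir-224	0.175638	1.10e-06	1.48e-05	-0.52346	1.97e-07	1.57e-05
FBN3	hsa-mir-224	0.135792	0.000173	0.001257	-0.28208	0.008121	0.065481
GPRIN2	hsa-mir-18b	0.090508	0.012555	0.045481	-0.3694	0.00043	0.007796
DSC2	hsa-mir-224	0.184346	3.09e-07	4.74e-06	-0.54743	4.09e-08	4.15e-06
BCL11A	hsa-mir-224	0.197716	3.88e-08	7.31e-07	-0.5425	5.71e-08	5.51e-06
KCNA3	hsa-mir-224	0.094124	0.009423	0.03605	-0.33546	0.001492	0.019649
ST8SIA1	hsa-mir-224	0.20703	8.38e-09	1.82e-07	-0.50737	5.29e-07	3.60e-05
CXCR6	hsa-mir-224	0.210274	4.83e-09	1.10e-07	-0.39647	0.000144	0.003366
RUNX3	hsa-mir-18b	0.103734	0.0042	0.018587	-0.26933	0.01165	0.083606
CD3D	hsa-mir-224	0.098973	0.00632	0.026008	-0.3057	0.003984	0.039943
FERMT1	hsa-mir-224	0.221817	6.32e-10	1.73e-08	-0.55639	2.20e-08	2.46e-06
C4A	hsa-mir-221	-0.12912	0.000359	0.002346	-0.367207	0.000468	0.00831
GRAMD2	hsa-mir-224	0.257596	5.52e-13	2.67e-11	-0.56696	1.03e-08	1.29e-06
PLEKHG4B	hsa-mir-224	0.188081	1.76e-07	2.85e-06	-0.55428	2.55e-08	2.79e-06
SLFN13	hsa-mir-224	0.118989	0.001014	0.005676	-0.55342	2.71e-08	2.93e-06
CD8B	hsa-mir-224	0.116876	0.001247	0.00676	-0.42097	4.90e-05	0.001447
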