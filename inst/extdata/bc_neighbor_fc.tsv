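# Tumor/normal fold changes of selected female-biased BC genes and their
# closest upstream/downstream neighbor genes. Zeroes encode missing data.
query	query_fc	upstream	upstream_fc	downstream	downstream_fc
RUNX3	1.070115	MIR4425	0	CLIC4	0.6956
KCNA3	0.88596	CD53	1.394738	KCNA2	0.137172
GPRIN2	0.806098	LOC102724488	0	NPY4R2	0.29892
CD3D	2.242477	CD3G	1.400305	CD3E	1.823305
ST8SIA1	0.502259	C2CD5	0.9289736	CMAS	1.383262
SLFN13	0.686176	SLFN12L	0.659786	SLFN12	0.726248
DSC2	0.894301	DSC1	0.135309	DSC3	0.531148
FBN3	4.680184	CERS4	1.9812753	CCL25	8.487113
BCL11A	0.797152	PAPOLG	0.816493	MIR4432HG	0
CD8B	1.703002	RGPD2	0	CD8A	1.511057
FERMT1	0.713849	CASC20	0	LRRN4	3.825036
CXCR6	1.464406	LZTFL1	0.902672	XCR1	1.150559
PLEKHG4B	1.2639	LRRC14B	1.273693	LRRC14B	1.273693
C4A	2.739965	STK19	1.613933	CYP21A1P	0
C4A	2.739965	STK19	1.613933	TNXB	0.071174
GRAMD2	0.549913	PKM	1.9346012	SENP8	0.9139357
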