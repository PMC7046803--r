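mir_id	region_type	ESR1	FOS	FoxA1	FoxA2	IRF1	JunD	RELA	Stat1
let-7a-5p	mir_enhancer	6	6	4	0	8	2	4	9
let-7a-5p	mir_promoter	3	3	3	0	5	0	3	5
let-7f-5p	mir_enhancer	7	7	8	7	9	11	10	8
let-7f-5p	mir_promoter	3	6	4	2	4	6	6	3
miR-150-5p	host_enhancer	19	11	10	8	11	10	6	8
miR-150-5p	host_promoter	6	3	2	3	3	1	0	2
miR-150-5p	mir_enhancer	8	4	7	4	3	3	6	3
miR-150-5p	mir_promoter	3	0	3	2	3	0	3	2
miR-151a-3p	host_enhancer	16	7	19	9	13	11	7	15
miR-151a-3p	host_promoter	3	1	6	1	4	3	2	6
miR-151a-3p	mir_enhancer	10	3	12	3	5	7	5	6
miR-151a-3p	mir_promoter	5	3	6	0	0	6	1	0
miR-21-5p	host_enhancer	4	10	6	16	17	13	9	10
miR-21-5p	host_promoter	2	0	3	5	4	3	1	0
miR-21-5p	mir_enhancer	2	7	2	8	11	8	4	4
miR-21-5p	mir_promoter	0	5	0	2	6	2	0	4
miR-30e-5p	host_enhancer	9	14	15	9	12	10	15	12
miR-30e-5p	host_promoter	3	2	6	0	5	1	4	4
miR-30e-5p	mir_enhancer	2	7	7	9	1	5	5	5
miR-30e-5p	mir_promoter	0	3	6	3	1	2	2	2
miR-423-5p	mir_enhancer	6	5	9	3	1	10	3	12
miR-423-5p	mir_promoter	4	4	6	0	0	4	3	6
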