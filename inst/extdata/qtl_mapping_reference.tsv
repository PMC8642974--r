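population	env	qtl	chrom	marker_interval	phys_start_mb	phys_end_mb	lod	pve	add	dom
BC3F2	14JH	qPEDS1.1	1	PM1-PM2	184.63	222.02	5.88	7.15	-0.08	0.07
BC3F2	14JH	qPEDS3.1	3	PM7-PM8	10.86	12.56	34.81	38.05	-0.18	-0.2
BC3F2	18WJ	qPEDS3.1	3	PM10-PM11	14.12	39.65	52.97	33.92	-0.34	-0.2
BC3F2	18WJ	qPEDS6.1	6	PM18-PM19	75.43	83.98	3.23	1.12	-0.04	-0.08
BC4F2	15WJ	qPEDS1.1	1	PM3-PM4	230.13	258.06	5.04	1.25	0.04	-0.05
BC4F2	15WJ	qPEDS1.2	1	PM4-PM27	258.06	281.12	3.98	1.12	-0.06	-0.01
BC4F2	15WJ	qPEDS3.1	3	PM30-PM10	11.89	14.12	31.17	33.91	-0.14	-0.14
BC4F2	15WJ	qPEDS6.1	6	PM18-PM19	75.43	83.98	8.2	3.26	0.07	-0.03
BC4F2	15WJ	qPEDS8.1	8	PM23-PM25	126.24	149.8	4.69	1.82	-0.05	0.03
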