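population	env	name	chrom1	pos1_cM	interval1	chrom2	pos2_cM	interval2	lod	pve	aa
BC3F2	14JH	EPqpeds-1	1	15	PM1-PM2	1	35	PM4-PM5	8.26	9.96	-0.14
BC3F2	14JH	EPqpeds-2	1	15	PM1-PM2	3	10	PM10-PM11	108.70	16.45	0.21
BC3F2	14JH	EPqpeds-3	3	5	PM9-PM10	3	25	PM13-PM14	31.53	12.25	0.00
BC3F2	14JH	EPqpeds-4	3	10	PM10-PM11	6	20	PM19-PM20	35.15	14.16	0.20
BC3F2	14JH	EPqpeds-5	3	10	PM10-PM11	8	20	PM24-PM25	24.67	13.98	0.17
BC3F2	18WJ	EPqpeds-6	1	15	PM26-PM4	1	30	PM26-PM4	30.39	6.05	0.09
BC3F2	18WJ	EPqpeds-2	1	20	PM26-PM4	3	15	PM29-PM7	97.00	7.15	0.05
BC3F2	18WJ	EPqpeds-7	3	5	PM29-PM7	3	25	PM10-PM11	89.50	9.45	0.15
BC3F2	18WJ	EPqpeds-8	1	20	PM26-PM4	6	5	PM17-PM18	7.22	4.62	0.07
BC3F2	18WJ	EPqpeds-9	3	15	PM29-PM7	6	10	PM17-PM18	85.49	7.30	0.06
BC3F2	18WJ	EPqpeds-10	6	10	PM17-PM18	6	15	PM18-PM19	6.98	3.85	-0.10
BC3F2	18WJ	EPqpeds-5	3	35	PM10-PM11	8	30	PM24-PM25	30.83	7.38	-0.20
BC4F2	15WJ	EPqpeds-1	1	50	PM3-PM4	1	70	PM4-PM27	10.54	3.87	0.08
BC4F2	15WJ	EPqpeds-11	3	5	PM7-PM30	3	50	PM15-PM32	10.30	10.53	0.10
BC4F2	15WJ	EPqpeds-12	1	50	PM3-PM4	6	15	PM18-PM19	5.36	7.54	-0.10
BC4F2	15WJ	EPqpeds-13	3	10	PM10-PM15	6	35	PM18-PM19	7.74	21.31	-0.01
BC4F2	15WJ	EPqpeds-14	6	15	PM18-PM19	6	55	PM19-PM20	5.47	4.32	0.11
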