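region	ba	class	cluster_id	k	x	y	z	sd_x	sd_y	sd_z	p_value
Middle cingulum	24	intention	53	17	1	19	39	4.6	4	3.4	0.03
Pre-supplementary motor area	6	intention	58	10	-3	12	53	7.1	6.5	2.5	0.04
Anterior insula	NA	intention	41	9	-41	17	-2	4.9	4.4	5	0.05
Superior parietal lobule	7	intention	45	9	18	-67	52	5.4	3.6	4.1	0.05
Inferior parietal lobule	40	intention	22	13	39	-45	41	4.4	5.3	3.8	0.05
Supplementary motor area	6	self_agency	24	5	-7	-4	69	4.7	5	5	0.02
Posterior insula	NA	self_agency	28	7	-41	2	1	4.4	4.1	5.9	0.02
Calcarine scissure	18	self_agency	59	5	18	-90	-1	6	4.2	8.4	0.02
Cerebellum	NA	self_agency	67	5	24	-53	-27	8.8	7.8	6.7	0.02
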