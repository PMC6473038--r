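region	ba	cluster_id	k	x	y	z	sd_x	sd_y	sd_z	validated
Inferior parietal lobule	40	37	7	-46	-48	51	7.7	3.9	6.3	TRUE
Superior temporal gyrus	22	6	7	45	-60	43	4.5	6.6	9.0	FALSE
Angular gyrus	39	33	9	54	-49	22	5.9	6.2	5.5	FALSE
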