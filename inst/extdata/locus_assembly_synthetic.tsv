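locus_id	taxon_id	contig_id	fraction
L01	t1	c1	0.85
L01	t2	c1	0.88
L01	t3	c1	0.93
L01	t4	c1	1.03
L01	t5	c1	0.83
L02	t1	c1	1.02
L02	t2	c1	1.04
L02	t3	c1	0.96
L02	t3	c2	0.88
L02	t4	c1	0.95
L02	t5	c1	0.8
L03	t1	c1	0.84
L03	t2	c1	0.83
L03	t3	c1	0.97
L03	t4	c1	0.88
L03	t5	c1	0.99
L04	t1	c1	0.91
L04	t2	c1	0.97
L04	t3	c1	1.05
L04	t4	c1	0.88
L04	t5	c1	0.99
L05	t2	c1	1.03
L05	t3	c1	0.84
L05	t4	c1	0.96
L05	t5	c1	0.81
L06	t1	c1	0.85
L06	t2	c1	0.88
L06	t3	c1	0.78
L06	t4	c1	0.88
L06	t5	c1	1.01
L07	t1	c1	0.87
L07	t2	c1	0.91
L07	t2	c2	0.5
L07	t3	c1	0.94
L07	t4	c1	0.91
L07	t5	c1	0.83
L08	t1	c1	1
L08	t2	c1	0.96
L08	t3	c1	0.99
L08	t4	c1	0.81
L08	t5	c1	0.98
L09	t1	c1	0.89
L09	t2	c1	1
L09	t3	c1	0.95
L09	t4	c1	0.99
L09	t4	c2	0.76
L09	t5	c1	0.93
L10	t1	c1	0.92
L10	t2	c1	0.99
L10	t3	c1	0.79
L10	t4	c1	0.91
L10	t5	c1	0.98
L11	t1	c1	0.97
L11	t2	c1	0.91
L11	t3	c1	1.01
L11	t4	c1	0.9
L11	t5	c1	0.85
L11	t5	c2	0.6
L12	t1	c1	0.8
L12	t3	c1	0.81
L12	t4	c1	0.87
L12	t5	c1	0.92
L12	t5	c2	0.9
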