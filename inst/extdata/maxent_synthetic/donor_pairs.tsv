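pair	a	b	value
3-6	A	A	0.00422100107848675
3-6	C	A	0.00140700035949558
3-6	G	A	0.04146602344097336
3-6	T	A	0.00375200095865489
3-6	A	C	0.00506520129418410
3-6	C	C	0.00168840043139470
3-6	G	C	0.04975922812916803
3-6	T	C	0.00450240115038587
3-6	A	G	0.12669128369455154
3-6	C	G	0.04223042789818383
3-6	G	G	0.55922692978828947
3-6	T	G	0.11261447439515694
3-6	A	T	0.00393290470543688
3-6	C	T	0.00131096823514563
3-6	G	T	0.03863583914677077
3-6	T	T	0.00349591529372167
4-5	A	A	0.47743317479451791
4-5	C	A	0.01987572319036918
4-5	G	A	0.20981681062032959
4-5	T	A	0.01987572319036918
4-5	A	C	0.04404385608382280
4-5	C	C	0.00223951810595709
4-5	G	C	0.02612771123616606
4-5	T	C	0.00223951810595709
4-5	A	G	0.05977879352885044
4-5	C	G	0.00335927715893564
4-5	G	G	0.04786868785239853
4-5	T	G	0.00335927715893564
4-5	A	T	0.04954933809430064
4-5	C	T	0.00251945786920173
4-5	G	T	0.02939367514068682
4-5	T	T	0.00251945786920173
6-7	A	A	0.00762690387564159
6-7	C	A	0.00915228465076991
6-7	G	A	0.11070708996166867
6-7	T	A	0.00762690387564159
6-7	A	C	0.00864382439239380
6-7	C	C	0.01037258927087256
6-7	G	C	0.12546803528989114
6-7	T	C	0.00864382439239380
6-7	A	G	0.00966074490914601
6-7	C	G	0.01159289389097521
6-7	G	G	0.14022898061811365
6-7	T	G	0.00966074490914601
6-7	A	T	0.02491455266042919
6-7	C	T	0.02989746319251502
6-7	G	T	0.46435900990650836
6-7	T	T	0.02144415420389354
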