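sample_label	class	cells_per_mL	antibody	count_per_mL
1e5 NS1 / anti-CD138	positive	1e5	anti-CD138	12123
1e5 NS1 / anti-CD138	positive	1e5	anti-CD138	14700
1e5 NS1 / anti-CD138	positive	1e5	anti-CD138	10367
3e4 NS1 / anti-CD138	positive	3e4	anti-CD138	3463
3e4 NS1 / anti-CD138	positive	3e4	anti-CD138	5173
3e4 NS1 / anti-CD138	positive	3e4	anti-CD138	6180
3e4 NS1 / anti-CD138	positive	3e4	anti-CD138	5070
1e4 NS1 / anti-CD138	positive	1e4	anti-CD138	2867
1e4 NS1 / anti-CD138	positive	1e4	anti-CD138	1223
1e4 NS1 / anti-CD138	positive	1e4	anti-CD138	1927
1e4 NS1 / anti-CD138	positive	1e4	anti-CD138	1597
3e3 NS1 / anti-CD138	positive	3e3	anti-CD138	467
3e3 NS1 / anti-CD138	positive	3e3	anti-CD138	630
3e3 NS1 / anti-CD138	positive	3e3	anti-CD138	517
3e3 NS1 / anti-CD138	positive	3e3	anti-CD138	607
1e3 NS1 / anti-CD138	positive	1e3	anti-CD138	500
1e3 NS1 / anti-CD138	positive	1e3	anti-CD138	977
1e3 NS1 / anti-CD138	positive	1e3	anti-CD138	280
1e3 NS1 / anti-CD138	positive	1e3	anti-CD138	353
1e5 NS1 / IpaD315	negative	NA	IpaD315	895
1e5 NS1 / IpaD315	negative	NA	IpaD315	60
1e5 NS1 / IpaD315	negative	NA	IpaD315	660
1e5 NS1 / IpaD315	negative	NA	IpaD315	637
1e5 NS1 / IpaD315	negative	NA	IpaD315	723
1e5 NS1 / IpaD315	negative	NA	IpaD315	313
1e5 NS1 / IpaD315	negative	NA	IpaD315	520
1e5 CHO / anti-CD138	negative	NA	anti-CD138	690
1e5 CHO / anti-CD138	negative	NA	anti-CD138	380
1e5 CHO / anti-CD138	negative	NA	anti-CD138	367
beads only / anti-CD138	negative	NA	anti-CD138	1665
beads only / anti-CD138	negative	NA	anti-CD138	375
beads only / anti-CD138	negative	NA	anti-CD138	2213
beads only / anti-CD138	negative	NA	anti-CD138	310
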