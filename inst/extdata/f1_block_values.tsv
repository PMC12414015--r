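block_id	individual_id	copy	variant_id	value
1	ind1	1	A	4
1	ind1	2	A	4
1	ind2	1	B	3
1	ind2	2	C	1
1	ind3	1	A	4
1	ind3	2	B	3
1	ind4	1	D	5
1	ind4	2	C	1
2	ind1	1	E	2
2	ind1	2	F	0
2	ind2	1	E	2
2	ind2	2	E	2
2	ind3	1	G	6
2	ind3	2	F	0
2	ind4	1	F	0
2	ind4	2	F	0
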