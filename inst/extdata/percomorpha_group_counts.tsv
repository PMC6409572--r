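# Published per-group OR gene counts (functional, pseudogenes in
# parentheses) for five Percomorpha fishes; input for cross-species
# pooling and sharing analyses.
species	alpha	beta	gamma	delta	epsilon	zeta	eta	non_or	total
Chinese_perch	0	6(1)	1	74(13)	8	13(13)	22(2)	1	123(29)
Seabass	0	5(1)	1	79(2)	6(1)	9	31	0	131(4)
Tongue_sole	0	1	0	62(4)	6	10	16	1	96(4)
Stickleback	0	1	0(3)	71(41)	4	18(4)	8(4)	0	102(52)
Fugu	0	1	0	30(25)	2(1)	4(2)	10(11)	0	47(39)
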