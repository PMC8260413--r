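chrom	start	end	n_snps	pi_T	pi_C	pi_B	fst_TC	fst_TB	fst_CB	fst	lsbl
chr1	1	50001	88	0.00063466666666666663	0.00066799999999999997	0.00064533333333333326	0.11312217194570136	0.1217257318952234	0.15706051873198848	0.059056806002143629	0.038893692554468132
chr1	25001	75001	89	0.00064799999999999992	0.00064799999999999992	0.00071333333333333329	0.098591549295774669	0.12660944206008584	0.11521739130434783	0.065537555228276881	0.054991800025756349
chr1	50001	100001	92	0.00066133333333333322	0.00068799999999999992	0.00070666666666666653	0.10487444608567212	0.064199395770392742	0.078757225433526007	0.045483259633607075	0.045158308211269427
chr1	75001	125001	48	0.00032533333333333329	0.00036533333333333334	0.00032933333333333322	0.12430167597765365	0.032894736842105282	0.093123209169054449	0.038870008496176715	0.032036601825352243
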