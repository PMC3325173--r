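gene	chrom	zygosity	var1	pos1	var2	pos2	cases	controls
UBE3B	12	homozygous	rs61748069	108420439	.	.	0	1
UBE3B	12	compound_heterozygous	rs61748069	108420439	var_12_109948232	108432615	1	0
CLTCL1	22	compound_heterozygous	rs5748024	17548288	rs2073738	17550956	10	4
CLTCL1	22	compound_heterozygous	rs5748024	17548288	var_22_19241688	17621688	1	0
CLTCL1	22	compound_heterozygous	rs2073738	17550956	var_22_19241688	17621688	1	0
CLTCL1	22	compound_heterozygous	var_22_19184109	17564109	rs1060374	17593033	1	0
CLTCL1	22	compound_heterozygous	var_22_19184113	17564113	var_22_19222211	17602211	1	0
CLTCL1	22	compound_heterozygous	var_22_19187289	17567289	rs117542241	17578017	0	1
CLTCL1	22	compound_heterozygous	rs34486244	17576615	rs45489597	17597422	0	1
CLTCL1	22	compound_heterozygous	rs35398725	17587491	rs45489597	17597422	1	0
CLTCL1	22	compound_heterozygous	rs5746697	17610365	var_22_19241688	17621688	1	0
CLTCL1	22	compound_heterozygous	var_22_19241688	17621688	rs3747059	17643214	1	0
NCKAP5L	12	compound_heterozygous	var_12_50186544	48472811	var_12_50187579	48473846	1	0
NCKAP5L	12	homozygous	var_12_50187579	48473846	.	.	1	0
NCKAP5L	12	compound_heterozygous	var_12_50187579	48473846	rs3741554	48476934	0	1
NCKAP5L	12	homozygous	rs3741554	48476934	.	.	2	0
ZNF18	17	compound_heterozygous	rs117755721	11822081	rs62621364	11822223	0	1
ZNF18	17	compound_heterozygous	rs117755721	11822081	var_17_11894428	11835153	0	1
ZNF18	17	homozygous	rs62621364	11822223	.	.	0	1
ZNF18	17	compound_heterozygous	var_17_11881611	11822336	var_17_11894428	11835153	1	0
ZNF18	17	homozygous	var_17_11894428	11835153	.	.	1	0
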