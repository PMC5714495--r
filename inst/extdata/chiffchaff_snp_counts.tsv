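comparison	chrom_class	shared	private_A	private_B	fixed	total
allopatry	autosome	2426608	2687834	1614661	9505	6738608
sympatry	autosome	3188645	1884193	1574541	0	6647379
allopatry	Z	27559	83921	52973	9444	173897
sympatry	Z	95951	57463	42697	0	196111
allopatry	all	2454167	2771755	1667634	18949	6912505
sympatry	all	3284596	1947656	1617238	0	6843490
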