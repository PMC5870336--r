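marker	chrom	start	end
BARCSOYSSR_13_1410	Gm13	35508707	35508744
BARCSOYSSR_13_1417	Gm13	35668210	35668255
BARCSOYSSR_13_1419	Gm13	35698358	35698407
BARCSOYSSR_13_1421	Gm13	35737431	35737464
BARCSOYSSR_13_1422	Gm13	35738647	35738680
BARCSOYSSR_13_1425	Gm13	35791995	35792026
BARCSOYSSR_13_1426	Gm13	35797040	35797063
BARCSOYSSR_13_1429	Gm13	35848793	35848826
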