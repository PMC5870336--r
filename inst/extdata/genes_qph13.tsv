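id	chrom	start	end	annotation
Glyma.13g248600	Gm13	35666896	35668024	Late embryogenesis abundant protein
Glyma.13g248700	Gm13	35668869	35672143	S-locus lectin protein kinase
Glyma.13g248800	Gm13	35677452	35681265	S-locus lectin protein kinase
Glyma.13g248900	Gm13	35685233	35690583	receptor kinase 3
Glyma.13g249000	Gm13	35692094	35696834	S-locus lectin protein kinase
Glyma.13g249100	Gm13	35700102	35701373	Unknown
Glyma.13g249200	Gm13	35701896	35706080	receptor kinase 3
Glyma.13g249300	Gm13	35712020	35716076	S-locus lectin protein kinase
Glyma.13g249400	Gm13	35719291	35721124	plant U-box 8
Glyma.13g249500	Gm13	35721467	35721860	Unknown
Glyma.13g249600	Gm13	35726229	35729214	Quinone reductase family protein
Glyma.13g249700	Gm13	35731494	35733559	Quinone reductase family protein
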