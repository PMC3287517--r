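sample	key	mid_fwd	mid_rev	primer_fwd	primer_rev
O_salicicola	TCAG	ATCGCG	CGCGAT	MGAGTTTGATCCTGGCTCAG	GCTGCCTCCCGTAGGAGT
O_rugosostriatus	TCAG	ATAGCC	GGCTAT	MGAGTTTGATCCTGGCTCAG	GCTGCCTCCCGTAGGAGT
O_sulcatus	TCAG	CCATAG	CTATGG	MGAGTTTGATCCTGGCTCAG	GCTGCCTCCCGTAGGAGT
O_armadillo	TCAG	CTTGAG	CTCAAG	MGAGTTTGATCCTGGCTCAG	GCTGCCTCCCGTAGGAGT
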