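sample	otu_id	read_count	match_group	closest_match
O_salicicola	JN563736	5516	blochmannia_like	AB478978 endosymbiont of Pedicinus obtusus / Candidatus Blochmannia
O_salicicola	JN563737	121	other	DQ417336 Schlegelella aquatica
O_salicicola	JN563738	96	other	FJ268988 uncultured Acinetobacter
O_salicicola	JN563739	69	other	CU927677 uncultured bacterium
O_salicicola	JN563740	48	other	FJ534956 uncultured bacterium
O_salicicola	JN563741	44	other	EF210100 Enterobacter hormaechei
O_salicicola	JN563742	34	other	AY923125 Streptococcus sp.
O_salicicola	JN563743	26	other	EU464962 uncultured bacterium
O_salicicola	JN563744	25	other	EU766013 uncultured bacterium
O_salicicola	JN563745	23	other	FJ393126 uncultured Bacteroides sp.
O_salicicola	JN563746	18	other	EU721814 uncultured epsilon proteobacterium
O_salicicola	JN563747	17	other	AY953252 Prevotella sp.
O_salicicola	JN563748	15	other	FJ799146 bacterium enrichment culture clone LA29
O_salicicola	JN563749	11	other	EU802152 uncultured bacterium
O_salicicola	JN563750	10	other	AY568512 Burkholderia fungorum
O_rugosostriatus	JN563751	7800	rickettsia	AB021128 Rickettsia sp.
O_rugosostriatus	JN563752	396	neoehrlichia	EF633744 Candidatus Neoehrlichia lotoris
O_rugosostriatus	JN563753	338	blochmannia_like	AB478978 endosymbiont of Pedicinus obtusus / Candidatus Blochmannia
O_rugosostriatus	JN563754	17	rickettsia	AB021128 Rickettsia sp.
O_rugosostriatus	JN563755	11	neoehrlichia	EF633744 Candidatus Neoehrlichia lotoris
O_rugosostriatus	JN563756	7	rickettsia	AB021128 Rickettsia sp.
O_rugosostriatus	JN563757	6	rickettsia	AB021128 Rickettsia sp.
O_rugosostriatus	JN563758	5	other	FJ868862 uncultured bacterium
O_rugosostriatus	JN563759	4	other	GQ845011 Nevskia sp.
O_sulcatus	JN563760	6358	rickettsia	AB021128 Rickettsia sp.
O_sulcatus	JN563761	35	neoehrlichia	EF633744 Candidatus Neoehrlichia lotoris
O_sulcatus	JN563762	19	neoehrlichia	EF633744 Candidatus Neoehrlichia lotoris
O_armadillo	JN563763	5900	blochmannia_like	AB478978 endosymbiont of Pedicinus obtusus / Candidatus Blochmannia
O_armadillo	JN563764	60	other	FJ823944 uncultured Comamonas sp.
O_armadillo	JN563765	54	other	FJ868862 uncultured bacterium
O_armadillo	JN563766	43	other	FJ823944 uncultured Comamonas sp.
O_armadillo	JN563767	35	other	FJ544375 Comamonas aquatica
O_armadillo	JN563768	31	other	EU560802 uncultured bacterium
O_armadillo	JN563769	23	other	DQ407746 primary endosymbiont of Liposcelis decolor
O_armadillo	JN563770	21	other	DQ469223 uncultured bacterium
O_armadillo	JN563771	21	other	GQ845011 Nevskia sp.
O_armadillo	JN563772	20	other	DQ860049 uncultured bacterium
O_armadillo	JN563773	11	other	AF006670 Shewanella putrefaciens
O_armadillo	JN563774	11	other	X82133 Shewanella putrefaciens
O_armadillo	JN563775	11	other	EU801479 uncultured bacterium
O_armadillo	JN563776	10	other	EF019306 uncultured proteobacterium
O_armadillo	JN563777	9	other	AY953252 Prevotella sp.
O_armadillo	JN563778	8	other	EU464962 uncultured bacterium
O_armadillo	JN563779	8	other	EU536078 uncultured bacterium
O_armadillo	JN563780	8	other	GQ068015 uncultured bacterium
O_armadillo	JN563781	8	other	L16490 Porphyromonas asaccharolytica
O_armadillo	JN563782	8	other	AY351787 uncultured marine bacterium
O_armadillo	JN563783	6	other	EF648074 uncultured Azoarcus sp.
O_armadillo	JN563784	5	other	EF648074 uncultured Azoarcus sp.
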