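ko	gene_symbol	pathway	description
K16567	exoQ	Wzx-Wzy	Exopolysaccharide production protein ExoQ (polymerase wzy)
K16695	wzxC	Wzx-Wzy	Lipopolysaccharide exporter (flippase wzx)
K03328	wzx	Wzx-Wzy	Polysaccharide transporter, PST family (flippase wzx)
K16692	wzc	Wzx-Wzy	Tyrosine-protein kinase Etk/Wzc (polysaccharide co-polymerase PCP)
K00903	epsB	Wzx-Wzy	Protein-tyrosine kinase (polysaccharide co-polymerase PCP)
K16554	exoP	Wzx-Wzy	Polysaccharide biosynthesis transport protein (polysaccharide co-polymerase PCP)
K13661	gumC	Wzx-Wzy	GumC protein (polysaccharide co-polymerase PCP)
K01991	wza	Wzx-Wzy	Polysaccharide biosynthesis/export protein (outer membrane transporter OPX)
K09689	kpsT	ABC-transport	Capsular polysaccharide transport system ATP-binding protein
K09688	kpsM	ABC-transport	Capsular polysaccharide transport system permease protein
K10107	kpsE	ABC-transport	Capsular polysaccharide transport system permease protein (PCP)
K16557	exoA	Glycosyltransferase	Succinoglycan biosynthesis protein ExoA
K16556	exoM	Glycosyltransferase	Succinoglycan biosynthesis protein ExoM
K16703	wcaL	Glycosyltransferase	Colanic acid/amylovoran biosynthesis glycosyltransferase
K13657	gumH	Glycosyltransferase	Alpha-1,3-mannosyltransferase
K00694	bcsA	Glycosyltransferase	Cellulose synthase (UDP-forming)
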