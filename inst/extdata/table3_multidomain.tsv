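species	accession	gi	source_db	n_p25_domains	other_domains	cdd	is_est
Chlamydomonas reinhardtii	XP_001691800	159467228	RefSeq	2	EFh	28933	FALSE
Volvox carteri	XP_002948912	302834700	RefSeq	2	EFh	28933	FALSE
Micromonas pusilla	XP_003058058	303277529	RefSeq	3	EFh,COG4942	28933,34550	FALSE
Micromonas pusilla	XP_003063447	303288317	RefSeq	1	EFh	28933	FALSE
Micromonas pusilla	XP_002506378	255088912	RefSeq	2	EFh	208857	FALSE
Micromonas pusilla	XP_002507907	255081370	RefSeq	2	EFh	28933	FALSE
Micromonas pusilla	XP_003061031	303283480	RefSeq	2			FALSE
Chlorella variabilis	EFN57882	307109645	GenBank	2			FALSE
Coccomyxa subellipsoidea	EIE25016	384251539	GenBank	2	EFh		FALSE
Ostreococcus lucimarinus	XP_001421186	145353793	RefSeq	2			FALSE
Albugo laibachii	CCA17632	325183175	GenBank	1	P-loopNTPase,DEXDc,HELICc	208973,197756,28960	FALSE
Ectocarpus siliculosus	CBN75312	299117356	GenBank	1	Znf_BBOX,IQ	206793,210118	FALSE
Ectocarpus siliculosus	CBJ49059	298705751	GenBank	1	zf-SNAP50_C,Znf_BBOX,IQ,WW	204865,206793,210118,206869	FALSE
Phytophthora infestans	XP_002905233	301112308	RefSeq	1	Znf_BBOX,IQ,COG5022	206793,210118,34627	FALSE
Phytophthora infestans	XP_002907084	301118713	RefSeq	1	Mcp5_PH	206947	FALSE
Phytophthora sojae	EGZ26181	348686366	GenBank	1	Znf_BBOX,IQ,COG5022	206793,210118,34627	FALSE
Naegleria gruberi	XP_002683090	291001047	RefSeq	1	Kelch	207702	FALSE
Naegleria gruberi	XP_002682916		RefSeq	1	PLN02919,PTPc	29029,206804	FALSE
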