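species	accession	gi	source_db	n_partial_domains	rossmann	is_est
Monosiga brevicollis	XP_001750206	167537072	RefSeq	1	yes	FALSE
Salpigoeca rosetta	EGD82798	326437228	GenBank	1	yes	FALSE
Batrachochytrium dendrobatidis	EGF79566	328769522	GenBank	2	yes,no	FALSE
Spizellomyces punctatus	SPPG_08463		Broad	2	yes	FALSE
Hyperamoeba dachnaya	EC854006	110160603	GenBank	3	yes	TRUE
Thecamonas trahens	AMSG_02233		Broad	4	yes	FALSE
Chlamydomonas reinhardtii	XP_001690551	159464643	RefSeq	1	yes	FALSE
Volvox carteri	XP_002946586	302830039	RefSeq	2	yes	FALSE
Lolium perenne	GR509039	300178892	GenBank	1	yes	TRUE
Aureococcus anophagefferens	EGB10333	323454463	GenBank	1	yes	FALSE
Ectocarpus siliculosus	CBN76131	299116327	GenBank	1	no	FALSE
Phytophthora infestans	XP_002907772	301120089	RefSeq	1	no	FALSE
Phytophthora ramorum	phyra80518		JGI	1	no	FALSE
Phytophthora sojae	EGZ29591	348689777	GenBank	1	no	FALSE
Giardia lamblia	XP_001705540	159110572	RefSeq	2	no,yes	FALSE
Giardia lamblia	GL50581_3979		GiardiaDB	2	no,yes	FALSE
Jakoba libera	EC691986	109799590	GenBank	3	no	TRUE
Seculamonas ecuadoriensis	EC817264	110123861	GenBank	3	no	TRUE
Trimastix pyriformis	EC840067	110146664	GenBank	3	yes	TRUE
Naegleria gruberi	D2VER9_NAEGR		UniProt	2	no	FALSE
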