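species	accession	gi	source_db	questionable	excluded
Drosophila melanogaster	NP_648370	24662040	RefSeq	FALSE	FALSE
Drosophila sechellia	XP_002029959	195326485	RefSeq	FALSE	FALSE
Drosophila simulans	XP_002084342	195589197	RefSeq	FALSE	FALSE
Drosophila erecta	XP_001972246	194868209	RefSeq	FALSE	FALSE
Drosophila yakuba	XP_002094265	195493080	RefSeq	FALSE	FALSE
Drosophila ananassae	XP_001957775	194750915	RefSeq	FALSE	FALSE
Drosophila willistoni	XP_002062203	195428283	RefSeq	FALSE	FALSE
Drosophila persimilis	XP_002025402	195169178	RefSeq	FALSE	FALSE
Drosophila pseudoobscura	XP_001353716	125979367	RefSeq	FALSE	FALSE
Drosophila mojavensis	XP_002007566	195126208	RefSeq	FALSE	FALSE
Drosophila virilis	XP_002047114	195376667	RefSeq	FALSE	FALSE
Drosophila grimshawi	XP_001983728	195012698	RefSeq	FALSE	FALSE
Anopheles gambiae	XP_556944	57918257	RefSeq	FALSE	FALSE
Culex quinquefasciatus	XP_001862283	170052572	RefSeq	FALSE	FALSE
Camponotus floridanus	EFN74475	307190439	GenBank	FALSE	FALSE
Solenopsis invicta	EFZ11240	322784183	GenBank	TRUE	FALSE
Danaus plexippus	EHJ66593	357609707	GenBank	FALSE	FALSE
Tribolium castaneum	EFA09619	270013171	GenBank	FALSE	FALSE
Tribolium castaneum	EEZ98749	270002302	GenBank	FALSE	FALSE
Ixodes scapularis	XP_002404704	241731346	RefSeq	FALSE	FALSE
Metaseiulus occidentalis	XP_003742023	391335280	RefSeq	FALSE	FALSE
Clonorchis sinensis	GAA47940	358339980	RefSeq	TRUE	TRUE
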