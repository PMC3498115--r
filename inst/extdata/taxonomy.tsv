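species	supergroup	megagroup	group	path
Drosophila melanogaster	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Hexapoda|Insecta|Endopterygota|Diptera
Drosophila sechellia	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Hexapoda|Insecta|Endopterygota|Diptera
Drosophila simulans	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Hexapoda|Insecta|Endopterygota|Diptera
Drosophila erecta	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Hexapoda|Insecta|Endopterygota|Diptera
Drosophila yakuba	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Hexapoda|Insecta|Endopterygota|Diptera
Drosophila ananassae	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Hexapoda|Insecta|Endopterygota|Diptera
Drosophila willistoni	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Hexapoda|Insecta|Endopterygota|Diptera
Drosophila persimilis	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Hexapoda|Insecta|Endopterygota|Diptera
Drosophila pseudoobscura	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Hexapoda|Insecta|Endopterygota|Diptera
Drosophila mojavensis	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Hexapoda|Insecta|Endopterygota|Diptera
Drosophila virilis	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Hexapoda|Insecta|Endopterygota|Diptera
Drosophila grimshawi	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Hexapoda|Insecta|Endopterygota|Diptera
Anopheles gambiae	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Hexapoda|Insecta|Endopterygota|Diptera
Culex quinquefasciatus	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Hexapoda|Insecta|Endopterygota|Diptera
Camponotus floridanus	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Hexapoda|Insecta|Endopterygota|Hymenoptera
Solenopsis invicta	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Hexapoda|Insecta|Endopterygota|Hymenoptera
Danaus plexippus	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Hexapoda|Insecta|Endopterygota|Lepidoptera
Tribolium castaneum	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Hexapoda|Insecta|Endopterygota|Coleoptera
Ixodes scapularis	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Chelicerata|Arachnida|Acari
Metaseiulus occidentalis	Opisthokonta	unikonts	Arthropoda	Metazoa|Arthropoda|Chelicerata|Arachnida|Acari
Clonorchis sinensis	Opisthokonta	unikonts	Platyhelminthes	Metazoa|Platyhelminthes|Trematoda
Homo sapiens	Opisthokonta	unikonts	Vertebrata	Metazoa|Chordata|Vertebrata
Caenorhabditis elegans	Opisthokonta	unikonts	Nematoda	Metazoa|Nematoda
Trichoplax adhaerens	Opisthokonta	unikonts	Placozoa	Metazoa|Placozoa
Suberites domuncula	Opisthokonta	unikonts	Porifera	Metazoa|Porifera
Monosiga brevicollis	Opisthokonta	unikonts	Choanomonada	Choanomonada
Salpigoeca rosetta	Opisthokonta	unikonts	Choanomonada	Choanomonada
Batrachochytrium dendrobatidis	Opisthokonta	unikonts	Fungi	Fungi|Chytridiomycota
Spizellomyces punctatus	Opisthokonta	unikonts	Fungi	Fungi|Chytridiomycota
Hyperamoeba dachnaya	Amoebozoa	unikonts	Mycetozoa	Mycetozoa
Thecamonas trahens	Apusozoa	unikonts	Apusomonadida	Apusomonadida
Chlamydomonas reinhardtii	Archaeplastida	photosynthetic	Chlorophyta	Chloroplastida|Chlorophyta|Chlorophyceae
Volvox carteri	Archaeplastida	photosynthetic	Chlorophyta	Chloroplastida|Chlorophyta|Chlorophyceae
Micromonas pusilla	Archaeplastida	photosynthetic	Chlorophyta	Chloroplastida|Chlorophyta|Prasinophyceae
Ostreococcus lucimarinus	Archaeplastida	photosynthetic	Chlorophyta	Chloroplastida|Chlorophyta|Prasinophyceae
Ostreococcus tauri	Archaeplastida	photosynthetic	Chlorophyta	Chloroplastida|Chlorophyta|Prasinophyceae
Chlorella variabilis	Archaeplastida	photosynthetic	Chlorophyta	Chloroplastida|Chlorophyta|Trebouxiophyceae
Coccomyxa subellipsoidea	Archaeplastida	photosynthetic	Chlorophyta	Chloroplastida|Chlorophyta|Trebouxiophyceae
Lolium perenne	Archaeplastida	photosynthetic	Charophyta	Chloroplastida|Charophyta
Oryza sativa	Archaeplastida	photosynthetic	Charophyta	Chloroplastida|Charophyta
Triticum aestivum	Archaeplastida	photosynthetic	Charophyta	Chloroplastida|Charophyta
Hordeum vulgare	Archaeplastida	photosynthetic	Charophyta	Chloroplastida|Charophyta
Cyanophora paradoxa	Archaeplastida	photosynthetic	Glaucophyta	Glaucophyta
Albugo laibachii	Chromalveolata	photosynthetic	Stramenopiles	Stramenopiles
Ectocarpus siliculosus	Chromalveolata	photosynthetic	Stramenopiles	Stramenopiles
Aureococcus anophagefferens	Chromalveolata	photosynthetic	Stramenopiles	Stramenopiles
Phytophthora infestans	Chromalveolata	photosynthetic	Stramenopiles	Stramenopiles|Oomycota
Phytophthora sojae	Chromalveolata	photosynthetic	Stramenopiles	Stramenopiles|Oomycota
Phytophthora ramorum	Chromalveolata	photosynthetic	Stramenopiles	Stramenopiles|Oomycota
Babesia bovis	Chromalveolata	photosynthetic	Alveolata	Alveolata|Apicomplexa
Toxoplasma gondii	Chromalveolata	photosynthetic	Alveolata	Alveolata|Apicomplexa
Plasmodium falciparum	Chromalveolata	photosynthetic	Alveolata	Alveolata|Apicomplexa
Tetrahymena thermophila	Chromalveolata	photosynthetic	Alveolata	Alveolata|Ciliophora
Paramecium tetraurelia	Chromalveolata	photosynthetic	Alveolata	Alveolata|Ciliophora
Paracercomonas marina	Rhizaria	photosynthetic	Cercozoa	Cercozoa
Giardia lamblia	Excavata	Excavata	Fornicata	Fornicata
Jakoba libera	Excavata	Excavata	Jakobida	Jakobida
Seculamonas ecuadoriensis	Excavata	Excavata	Jakobida	Jakobida
Malawimonas californiana	Excavata	Excavata	Malawimonas	Malawimonas
Trimastix pyriformis	Excavata	Excavata	Preaxostyla	Preaxostyla
Naegleria gruberi	Excavata	Excavata	Heterolobosea	Heterolobosea
Trypanosoma brucei	Excavata	Excavata	Euglenozoa	Euglenozoa|Kinetoplastea
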