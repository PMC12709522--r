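name	forward_primer	reverse_primer	type	chrom	start	end	reported_length_bp
n1	(TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG)TATTATGTTATGGGAGGTTGTTTYGAG	(GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG)ACRTAAAACTTAAAACTCTTACAAATACT	Hypo	chr10	3283768	3284144	289
n2	(TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG)TAAAAGGGAAATTGGATTTTTAGAGAGA	(GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG)ATCCATCCATTTTAATAATAAACACCAC	Hypo	chr9	7209139	7209478	208
n3	(TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG)TGTGTTTGGTTTTTTAATAAAGGAAAGG	(GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG)CTTAAACTTCCCCTTCTCCTTCTC	Hypo	chr16	88677634	88677983	267
n4	(TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG)TTTTTTTTGTTGGTAGTTGGAGGTAG	(GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG)CACAAAATAACAAATAACCTTACTCCCT	Hypo	chr6	112086098	112086366	187
n5	(TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG)AGGTATGAAAGGTTAGGTTGTTTTTTTA	(GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG)CTCCTTTTCCCATTTTAAACACAATTAT	Hypo	chr6	128387907	128388072	138
n6	(TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG)TAGATGAATTTGTAAAAGGGAAATTGGA	(GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG)CATCCATTTTAATAATAAACACCACACC	Hypo	chr9	7209139	7209478	217
n7	(TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG)TAGGAGGTTTTGGCGTTCGGTTAGTTTT	(GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG)ACCAAAAAAAACTCCTACTACTAAAACA	Hyper	chr14	70039000	70039294	268
n8	(TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG)AATTGGTAGGTTTGTAGTAGGAGGT	(GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG)TACAAAATAAACTAAAACTATTCCACRC	Hyper	chr17	72353358	72353665	204
n9	(TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG)TTGTTTTTTAGTTTTGTAYGTTTTTTTT	(GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG)TCRTAAATTCAATACCATTAATAACCAA	Hypo	chr1	568193	568528	224
n10	(TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG)AGGGAAGGGAATTTTAATTGTTTTTTTT	(GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG)ACTTAAAAACATATTTTAAATTTTTATCCCTTACA	Hypo	chr2	201321569	201321769	201
n11	(TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG)ATTTGATTTTGTGGTAGTGGA	(GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG)AAAATCCCCACCTCTACTTAA	Hypo	chr16	72460052	72460163	111
n12	(TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG)TATATGTGTGTAGGTTGAATAAAAT	(GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG)TCCATTTCATATCAATACTAATATT	Hypo	chr10	3283855	3283972	117
n13	(TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG)TTTAGTGTTAGAATTGAAAGAGTAGA	(GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG)TTAACCTTAACTATATCTAACAAAAA	Hypo	chr1	10239929	10240207	210
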