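component_id	name	kind	category	taste_class
No.1	Ethanol	VF	alcohol	NA
No.2	Phenethyl alcohol	VF	alcohol	NA
No.3	Ethyl acetate	VF	ester	NA
No.4	Ethyl isobutyrate	VF	ester	NA
No.5	Ethyl butyrate	VF	ester	NA
No.6	Ethyl 2-methylbutyrate	VF	ester	NA
No.7	Ethyl caproate/4-methyl-Pentanoic acid, ethyl ester	VF	ester	NA
No.8	Methyl benzoate	VF	ester	NA
No.9	2,6-Di-tert-butyl-4-methylphenol	VF	ester	NA
No.10	Methyl hexadecanoate	VF	ester	NA
No.11	Ethyl palmitate	VF	ester	NA
No.12	Octadecenoic acid methyl ester	VF	ester	NA
No.13	Methyl linoleate	VF	ester	NA
No.14	Ethyl oleate	VF	ester	NA
No.15	9,12-Octadecadienoic acid (Z, Z)-, ethyl ester	VF	ester	NA
No.16	(Z, Z, Z)-9,12,15-Octadecatrienoic acid, ethyl ester	VF	ester	NA
No.17	2,5-Dimethyl pyrazine	VF	pyrazine	NA
No.18	2,3,5-Trimethylpyrazine	VF	pyrazine	NA
No.19	3-ethyl-2,5-dimethyl-Pyrazine	VF	pyrazine	NA
No.20	Tetramethylpyrazine	VF	pyrazine	NA
No.21	3,5-diethyl-2-methyl-Pyrazine	VF	pyrazine	NA
No.22	Hexamethylcyclotrisiloxane	VF	alkane	NA
No.23	Octamethylcyclotetrasiloxane	VF	alkane	NA
No.24	Undecane	VF	alkane	NA
No.25	Isovaleraldehyde	VF	aldehyde	NA
No.26	Benzaldehyde	VF	aldehyde	NA
No.27	Phenylacetaldehyde	VF	aldehyde	NA
No.28	l-Caryophyllene	VF	aldehyde	NA
No.29	Guaiacol	VF	phenol	NA
No.30	2-Ethylphenol	VF	phenol	NA
No.31	Cocal	VF	phenol	NA
No.32	Butyric acid	VF	acid	NA
No.33	Isovaleric acid	VF	acid	NA
No.34	DL-2-Methylbutyric acid	VF	acid	NA
No.35	4-Methylvaleric acid	VF	acid	NA
No.36	Palmitic acid	VF	acid	NA
No.37	Linoleic acid	VF	acid	NA
No.38	Tetrahydrothiophene	VF	other	NA
No.39	2-Chloro-4-(4-methoxyphenyl)-6-(4-nitrophenyl) pyrimidine	VF	other	NA
No.40	1,3-diphenyl-1-(trimethylsilyioxy)-1-Heptene	VF	other	NA
No.41	alpha-ethylidene-Benzeneacetaldehyde	VF	other	NA
No.42	Ethyl 3-phenylpropionate	VF	other	NA
Glu	Glutamic acid	AA	NA	umami
Asp	Aspartic acid	AA	NA	umami
Ala	Alanine	AA	NA	sweet
Gly	Glycine	AA	NA	sweet
Ser	Serine	AA	NA	sweet
Thr	Threonine	AA	NA	sweet
Arg	Arginine	AA	NA	bitter
His	Histidine	AA	NA	bitter
Ile	Isoleucine	AA	NA	bitter
Leu	Leucine	AA	NA	bitter
Met	Methionine	AA	NA	bitter
Trp	Tryptophan	AA	NA	bitter
Tyr	Tyrosine	AA	NA	bitter
Val	Valine	AA	NA	bitter
Lys	Lysine	AA	NA	unclassified
Phe	Phenylalanine	AA	NA	unclassified
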