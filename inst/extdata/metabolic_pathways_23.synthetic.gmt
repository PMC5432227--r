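Glycolysis	synthetic reconstruction: glucose to pyruvate	HK1	HK2	GPI	PFKL	PFKM	PFKP	ALDOA	ALDOB	ALDOC	TPI1	GAPDH	PGK1	PGAM1	ENO1	ENO2	PKM
Gluconeogenesis	synthetic reconstruction: pyruvate/oxaloacetate to glucose	PCK1	PCK2	FBP1	FBP2	G6PC	PC
Pentose Phosphate Pathway	synthetic reconstruction: oxidative and non-oxidative PPP	G6PD	PGLS	PGD	RPIA	RPE	TKT	TALDO1
TCA Cycle	synthetic reconstruction: citrate cycle core enzymes	CS	ACO1	ACO2	IDH1	IDH2	IDH3A	IDH3B	IDH3G	OGDH	SUCLA2	SUCLG1	SDHA	SDHB	SDHC	SDHD	FH	MDH1	MDH2
Pyruvate to Acetyl CoA	synthetic reconstruction: PDH complex and regulators	PDHA1	PDHB	DLAT	DLD	PDHX	PDK1	PDP1
Lactate generation	synthetic reconstruction: lactate dehydrogenase and export	LDHA	LDHB	SLC16A1	SLC16A3
Glutaminolysis	synthetic reconstruction: glutamine to alpha-ketoglutarate	GLS	GLS2	GLUD1	GLUD2	GOT1	GOT2	GLUL
One-carbon metabolism	synthetic reconstruction: serine/folate one-carbon cycle	PHGDH	PSAT1	PSPH	SHMT1	SHMT2	MTHFD1	MTHFD2	MTHFD1L	MTHFR	MTR	DHFR	TYMS	GART	ATIC
Proline Synthesis	synthetic reconstruction: glutamate/ornithine to proline	ALDH18A1	PYCR1	PYCR2	PYCRL	OAT
Proline Degradation	synthetic reconstruction: mitochondrial proline catabolism	PRODH	ALDH4A1
Fatty Acid Activation	synthetic reconstruction: acyl-CoA synthetases	ACSL1	ACSL3	ACSL4	ACSL5	ACSL6	SLC27A2
Fatty Acid B-oxidation	synthetic reconstruction: carnitine shuttle and beta-oxidation	CPT1A	CPT1B	CPT2	ACADM	ACADL	ACADVL	ACADS	ECHS1	HADHA	HADHB	ACAA2
Lipogenesis	synthetic reconstruction: de novo fatty acid synthesis	ACLY	ACACA	ACACB	FASN	SCD	ELOVL6	MLYCD
Cholesterogenesis	synthetic reconstruction: mevalonate to cholesterol	HMGCS1	HMGCR	MVK	PMVK	MVD	IDI1	FDPS	FDFT1	SQLE	LSS	DHCR7	DHCR24
Ketogenesis	synthetic reconstruction: ketone body synthesis	HMGCS2	HMGCL	BDH1	ACAT1
Ketolysis	synthetic reconstruction: ketone body utilization	OXCT1	OXCT2	BDH2	ACAT2
Choline_PhosphoCholine	synthetic reconstruction: choline uptake and phosphorylation	CHKA	CHKB	SLC44A1	SLC44A2	PLD1	PLD2
CDP-Choline	synthetic reconstruction: Kennedy pathway to phosphatidylcholine	PCYT1A	PCYT1B	CHPT1	CEPT1
Oxpho I Complex	synthetic reconstruction: NADH dehydrogenase subunits	NDUFA1	NDUFA2	NDUFB1	NDUFS1	NDUFS2	NDUFS3	NDUFV1	NDUFV2
Oxpho II Complex	synthetic reconstruction: succinate dehydrogenase subunits	SDHA	SDHB	SDHC	SDHD
Oxpho III Complex	synthetic reconstruction: cytochrome bc1 complex subunits	UQCRC1	UQCRC2	UQCRFS1	UQCRB	UQCRQ	UQCRH	CYC1
Oxpho IV Complex	synthetic reconstruction: cytochrome c oxidase subunits	COX4I1	COX5A	COX5B	COX6A1	COX6B1	COX6C	COX7A2	COX7B	COX8A
Oxpho V Complex	synthetic reconstruction: ATP synthase subunits	ATP5F1A	ATP5F1B	ATP5F1C	ATP5F1D	ATP5F1E	ATP5PB	ATP5MC1	ATP5PD
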