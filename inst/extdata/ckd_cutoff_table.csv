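role,target,pdb_id,positive_drug,cutoff,n_effective
known,CA2,1BN3,Topiramate,-8.4,10
known,RAF1,1C1Y,Sorafenib,-9.6,12
known,MIF,1GCZ,ethyl 7-hydroxy-2-oxochromene-3-carboxylate,-8.9,10
known,HGF,1GMO,"N,O6-Disulfo-Glucosamine",-7,79
known,HIF1A,1H2K,Everolimus,-6.3,66
known,EPHX2,1ZD3,4-{[(cyclohexylamino)carbonyl]amino} butanoic acid,-7.4,15
known,CA12,1JD0,Hydrochlorothiazide,-6.9,26
known,PPARG,1K74,Fenofibrate,-9.4,39
known,ACE,1O86,Candoxatril,-9,74
known,MAOB,1OJ9,Pargyline,-9.2,39
known,MAPK1,1PME,4-[4-(4-fluorophenyl)-2-[4-[(S)-methylsulfinyl]phenyl]-1H-imidazol-5-yl] pyridine,-9.4,27
known,KIT,1T46,Sorafenib,-10.1,34
known,TYMP,1UOU,"Chloro-6-[(2-Iminopyrrolidin-1-Yl)Methyl]Pyrimidine-2,4(1 h,3 h)-Dione",-7.7,76
known,MMP12,1UTT,"(6R)-4-benzyl-6-(1-methyl-2,2-dioxido-1,3-dihydro-2,1-benzisothiazol-5-yl)morpholin-3-one",-10.6,6
known,ADRB2,3D4S,Carvedilol,-9.3,45
known,ADORA2A,3EML,Mefloquine,-9.8,71
known,CCR1,1Y5D,Maraviroc,-8.2,35
known,MAPK14,1ZZ2,"N-[(3z)-5-Tert-Butyl-2-Phenyl-1,2-Dihydro-3h-Pyrazol-3-Ylidene]-N'-(4-Chlorophenyl)Urea",-8.4,14
known,ITGAL,1CQP,Lovastatin,-7.2,0
known,AVPR1A,1YTV,Conivaptan,-10.5,20
known,PGF,1FZV,Suplatast tosylate,-5,25
known,TGFB1,1KLD,,NO ligand,
known,TNFSF5,1I9R,,NO ligand,
known,NFKB1,1NFI,,NO ligand,
known,CA4,1ZNC,,NO ligand,
known,CCL2,2BDN,,NO ligand,
known,POLR2D,2C35,,NO ligand,
known,CA9,2HKF,,NO ligand,
known,SERPINE1,1OC0,,NO ligand,
known,AKT1,1AO2,,NO ligand,
known,TGM2,2Q3Z,,NO ligand,
putative,BTK,3OCS,Staurosporine,-9.6,53
putative,CCL5,1U4M,Heparin_Disaccharide_I-S,-6,15
putative,EGFR,2GS7,Flavopiridol,-9,19
putative,ESR1,3Q97,Estradiol,-10,1
putative,HSPA8,3FZK,"(2R,3R,4S,5R)-2-[6-amino-8-[(3,4-dichlorophenyl)methylamino]purin-9-yl]-5-(hydroxymethyl)oxolane-3,4-diol",-8.2,34
putative,INSR,2HR7,Hydrochloride,-9.5,21
putative,LCK,3AC1,"N-(2-chloro-6-methylphenyl)-8-[(3S)-3-methylpiperazin-1-yl]imidazo[1,5-a]quinoxalin-4-amine",-8.2,60
putative,HNF4A,1PZL,1_methyl_2-nitro_benzo[e]benzofuran,-7.4,79
putative,NR3C1,3K22,Flunisolide,-10,26
putative,PIK3CA,3HHM,Wortmannin,-9.1,20
putative,PLAT,1A5H,Iloprost,-8.5,87
putative,ACTN1,1RX0,Methacrylyl-Coenzyme_A,-9,16
putative,PTPN1,1BZH,(Oxalyl-Amino)-Naphthalene-2-Carboxylic_Acid,-8,19
putative,PRKCB,2I0E,Vitamin_E,-9.7,13
putative,VHL,3ZRC,"4-((naphthalen-2-ylamino)methyl)benzene-1,2-diol",-7.7,21
putative,FYN,1AOT,"2,5,8,11-Tetraoxadodecane",-6.6,29
putative,CCR5,2RLL,,NO ligand,
putative,FCGR2B,2FCB,,NO ligand,
putative,FN1,3MQL,,NO ligand,
putative,IGHG1,1ZVO,,NO ligand,
putative,SLC4A1,1BTT,,NO ligand,
putative,STAT1,1BF5,,NO ligand,
putative,JUN,1FOS,,NO ligand,
putative,KIAA0101,No PDB data,,,
putative,COMT,No PDB data,,,
putative,DCN,No PDB data,,,
putative,CLU,No PDB data,,,
putative,TGFBR1,No PDB data,,,
putative,IL8,No PDB data,,,
putative,APOA1,No PDB data,,,
putative,STAT5B,No PDB data,,,
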