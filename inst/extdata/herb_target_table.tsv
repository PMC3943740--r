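herb	target
SM	PLAT
SM	FYN
SM	CA2
SM	PTPN1
SM	RAF1
SM	PGF
SM	MIF
SM	HGF
SM	HIF1A
SM	CA12
SM	PPARG
SM	ACE
SM	MAOB
SM	MAPK1
SM	HNF4A
SM	ACTN1
SM	KIT
SM	CCL5
SM	TYMP
SM	MMP12
SM	CCR1
SM	AVPR1A
SM	EPHX2
SM	MAPK14
SM	EGFR
SM	INSR
SM	PRKCB
SM	LCK
SM	ADRB2
SM	ADORA2A
SM	HSPA8
SM	PIK3CA
SM	NR3C1
SM	ESR1
SM	VHL
AR	PLAT
AR	FYN
AR	CA2
AR	PTPN1
AR	RAF1
AR	PGF
AR	MIF
AR	HGF
AR	HIF1A
AR	CA12
AR	PPARG
AR	ACE
AR	MAOB
AR	MAPK1
AR	HNF4A
AR	ACTN1
AR	KIT
AR	CCL5
AR	TYMP
AR	MMP12
AR	CCR1
AR	AVPR1A
AR	EPHX2
AR	MAPK14
AR	EGFR
AR	INSR
AR	PRKCB
AR	LCK
AR	ADRB2
AR	ADORA2A
AR	HSPA8
AR	PIK3CA
AR	NR3C1
AR	VHL
AR	BTK
RR	ACTN1
RR	ADORA2A
RR	ACE
RR	CA2
RR	CA12
RR	CCR1
RR	VHL
RR	EGFR
RR	FYN
RR	NR3C1
RR	HSPA8
RR	HGF
RR	HNF4A
RR	HIF1A
RR	INSR
RR	MIF
RR	KIT
RR	MAPK1
RR	MAPK14
RR	MAOB
RR	PIK3CA
RR	PGF
RR	PLAT
RR	PTPN1
RR	LCK
RR	RAF1
RR	CCL5
RR	EPHX2
RR	TYMP
RR	BTK
RR	ADRB2
CS	PLAT
CS	HGF
CS	HIF1A
CS	PPARG
CS	ACE
CS	MAOB
CS	MAPK1
CS	HNF4A
CS	ACTN1
CS	KIT
CS	CCL5
CS	TYMP
CS	MMP12
CS	MAPK14
CS	EGFR
CS	INSR
CS	LCK
CS	ADRB2
CS	HSPA8
CS	PIK3CA
CS	NR3C1
CS	BTK
CS	VHL
CR	PLAT
CR	FYN
CR	RAF1
CR	PGF
CR	HGF
CR	HIF1A
CR	CA12
CR	PPARG
CR	HNF4A
CR	KIT
CR	TYMP
CR	EPHX2
CR	INSR
CR	ADRB2
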