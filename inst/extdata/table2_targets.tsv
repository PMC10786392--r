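gene_id	set	description
DNAJC10	miR-34c	DnaJ heat shock protein family (Hsp40) member C10
NRDC	miR-34c	nardilysin convertase
URI1	miR-34c	URI1 prefoldin like chaperone
POLR1F	miR-34c	RNA polymerase I subunit F
DEK	miR-34c	DEK proto-oncogene
UBA2	miR-34c	ubiquitin like modifier activating enzyme 2
CCDC59	miR-34c	coiled-coil domain containing 59
CEP55	miR-34c	centrosomal protein 55
FRA10AC1	miR-34c	FRA10A associated CGG repeat 1
KIN	miR-34c	Kin17 DNA and RNA binding
GKAP1	miR-34c	G kinase anchoring protein 1
FAM204A	miR-34c	family with sequence similarity 204 member A
TPM4	miR-34c	tropomyosin 4
ARL13B	miR-34c	ADP ribosylation factor like GTPase 13B
CCDC43	miR-34c	coiled-coil domain containing 43
ZNF320	miR-34c	zinc finger protein 320
JRKL	miR-34c	JRK like
SEPTIN10	miR-34c	septin 10
ZNF568	miR-34c	zinc finger protein 568
RUFY2	miR-34c	RUN and FYVE domain containing 2
HMGB1P6	miR-34c	high mobility group box 1 pseudogene 6
AC245060.7	miR-34c	lncRNA
CSDE1	miR-449a	cold shock domain containing E1
ADSS2	miR-449a	adenylosuccinate synthase 2
EIF4B	miR-449a	eukaryotic translation initiation factor 4B
APLP2	miR-449a	amyloid beta precursor like protein 2
TXLNG	miR-449a	taxilin gamma
HSP90AB1	miR-449a	heat shock protein 90 alpha family class B member 1
ST13	miR-449a	ST13 Hsp70 interacting protein
RHOV	miR-449a	ras homolog family member V
GTPBP4	miR-449a	GTP binding protein 4
CCDC47	miR-449a	coiled-coil domain containing 47
CCDC34	miR-449a	coiled-coil domain containing 34
METAP2	miR-449a	methionyl aminopeptidase 2
CMAS	miR-449a	cytidine monophosphate N-acetylneuraminic acid synthetase
IFT57	miR-449a	intraflagellar transport 57
NCBP2	miR-449a	nuclear cap binding protein subunit 2
CACYBP	miR-449a	calcyclin binding protein
SET	miR-449a	SET nuclear proto-oncogene
ZCCHC9	miR-449a	zinc finger CCHC-type containing 9
UTP3	miR-449a	UTP3 small subunit processome component
HSD17B4	miR-449a	hydroxysteroid 17-beta dehydrogenase 4
CALCOCO2	miR-449a	calcium binding and coiled-coil domain 2
C1orf131	miR-449a	chromosome 1 open reading frame 131
TPBG	miR-449a	trophoblast glycoprotein
CCT6A	miR-449a	chaperonin containing TCP1 subunit 6A
EBAG9	miR-449a	estrogen receptor binding site associated antigen 9
CETN3	miR-449a	centrin 3
ZNF22-AS1	miR-449a	ZNF22 antisense RNA 1
UPF3A	miR-449a	UPF3A regulator of nonsense mediated mRNA decay
TAF7	miR-449a	TATA-box binding protein associated factor 7
ZFP3	miR-449a	ZFP3 zinc finger protein
NPM1	miR-449a	nucleophosmin 1
KATNA1	miR-449a	katanin catalytic subunit A1
GTF2F2	miR-449a	general transcription factor IIF subunit 2
FAM3C	miR-449a	FAM3 metabolism regulating signaling molecule C
NUDT16	miR-449a	nudix hydrolase 16
ZNF830	miR-449a	zinc finger protein 830
TYW1	miR-449a	tRNA-yW synthesizing protein 1 homolog
DHX16	miR-449a	DEAH-box helicase 16
GET1-SH3BGR	miR-449a	GET1-SH3BGR readthrough
STK3	shared	serine/threonine kinase 3
PPWD1	shared	peptidylprolyl isomerase domain and WD repeat containing 1
C9orf78	shared	chromosome 9 open reading frame 78
ANP32B	shared	acidic nuclear phosphoprotein 32 family member B
PRPF18	shared	pre-mRNA processing factor 18
STRN3	shared	striatin 3
L3MBTL3	shared	L3MBTL histone methyl-lysine binding protein 3
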