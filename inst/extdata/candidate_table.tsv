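gene	mutation_type	transcript	exon	coding	protein	bd_linked
RAB3GAP1	SNV-missense	NM_001172435	25	C2821G	P941A	0
GPD2	SNV-missense	NM_001083112	9	A1096G	I366V	0
CCR4	SNV-missense	NM_005508	2	G424A	A142T	0
SCN10A	SNV-missense	NM_006514	13	C2015T	T672I	0
GOLIM4	SNV-missense	NM_014498	4	A334G	S112G	0
ADH5	SNV-missense	NM_000671	4	C328T	L110F	0
PELO	SNV-missense	NM_015946	2	A716G	K239R	0
TTC37	SNV-missense	NM_014639	11	G829A	G277S	0
NEU1	SNV-missense	NM_000434	4	C640T	R214C	1
MDN1	SNV-missense	NM_014611	63	C10551A	D3517E	0
SPAG1	SNV-missense	NM_172218	9	C844T	R282C	0
APTX	SNV-missense	NM_175073	9	C952A	R318S	0
AKNA	SNV-missense	NM_030767	3	G577C	V193L	0
COG6	SNV-missense	NM_020751	12	A1145G	K382R	0
MAP3K9	SNV-missense	NM_033141	13	A2936G	N979S	0
YLPM1	SNV-missense	NM_019589	5	T3638C	M1213T	0
PKD1L2	SNV-unknown	unknown	16	unknown	unknown	0
CCDC40	SNV-missense	NM_017950	20	C3355T	P1119S	0
TBCD	SNV-missense	NM_005993	20	C1810T	P604S	0
CYB5A	SNV-missense	NM_148923	1	G25T	V9L	0
ELANE	SNV-missense	NM_001972	2	C100T	R34W	0
DOT1L	SNV-missense	NM_032482	20	T2250G	C750W	0
TMPRSS15	SNV-missense	NM_002772	4	G428T	G143V	0
GOLGB1	INDEL-frameshift deletion	NM_004487	15	8743delC	H2915fs	1
EYS	INDEL-nonframeshift deletion	NM_001292009	19	2953_2961del	TDG985_987del	0
TBC1D16	INDEL-frameshift deletion	NM_019020	5	1015delC	H339fs	1
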