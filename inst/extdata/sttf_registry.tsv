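# Registry of published single-target transcription factors of E. coli K-12.
# Transcribed from the printed list (two versions: the earlier 13-name list
# and the 11 newly reported factors). org: type_A = TF gene adjacent to its
# target genes, type_B = separated. in_counts = FALSE marks rows carried as
# annotated discrepancies (present only in the printed table, not in the
# in-text name lists on which the totals are based).
tf_name	alternative_name	family	org	effector	function_desc	target_operons	version	in_counts	notes
BetI		TetR	type_A	Choline	Betaine inhibitor	betIbetBA/betT	1	TRUE	
CecR	YbiH	TetR	type_A		Cefoperazone-chloramphenicol sensitivity	cecRybhRGFSR/rhlE	1	TRUE	
DecR	YbaO	AsnC	type_B		Regulator of cysteine detoxification	cyuPA	1	TRUE	
KdpE		OmpR	type_A	AcP (KdpD)	K+ uptake operon regulator	kdpFABCD/kdpE	1	TRUE	
LacI		GalR/LacI	type_A	Allolactose	Lac operon regulator	lacZYA/lacI	1	TRUE	
MarR		MarR	type_A	Salicylate	Multiple antibiotic resistance regulator	marC/marRmarAB	1	TRUE	
NanR		GntR	type_A	N-Acetylneuraminate	N-Acetylneuramic acid regulator	nanATEK/nanR	1	TRUE	
NemR	YdhM	TetR	type_A		Regulator of N-ethylmaleimide resistance	rplB/rpiRalsBACE	1	FALSE	table-only row; absent from the in-text 13-name list, excluded from totals
NimR	YeaM	AraC	type_A		Regulator of 2-nitroimidazole resistance	nimR/nimT	1	TRUE	
RpiR		RpiR	type_A	D-Allose	Ribose utilization regulator	rplR/rpiB	1	TRUE	
TorR		OmpR	type_A	AcP (TorS)	TMAO reductase regulator	torR/torC	1	TRUE	
UlaR		DeoR	type_A		L-Ascorbate utilization regulator	ulaR/ulaG/ulaABCDEF	1	TRUE	
UxuR		GntR	type_A	Galacturonate, Glucuronate	Hexuronate regulator	gntP/uxuABuxuR	1	TRUE	
XylR	XynR/YagI	IclR	type_A		Regulator of xylonate catabolism	yagEF/xynR	1	TRUE	listed as XylR in the text, XynR (=YagI) in the table
CsqR	YihW	DeoR	type_A		Sulfoquinovose catabolism regulator	squUTS/squVcsqR	2	TRUE	spelled CsgR in the printed table
CusR		OmpR	type_A	AcP (CusS)	Cu-sensing regulator	cusRcusS/cusCFBA	2	TRUE	conditional: single-target only unphosphorylated
HprR	YedW	OmpR	type_A	AcP (HprS)	Hydrogen peroxide response regulator	hprRhprS/hiuH, cusRS/cusCFBA	2	TRUE	
NorR	YgaA	NtrC	type_A		NO reduction detoxification regulator	norR/norVW	2	TRUE	
PepA		Trigger	type_B		Peptidase trigger regulator	nfeF/nfeR	2	TRUE	
PutA		Trigger	type_A		Proline utilization trigger regulator	putA/putP	2	TRUE	
QseA		LysR	type_A	aromatic carboxylic acid	Quorum-sensing regulator A	aaeXAB/qseA	2	TRUE	conditional: single-target only effector-bound
RspR	YdfH	GntR	type_B		Mannonate utilization regulator	rspAB	2	TRUE	
UvrY		LuxR	type_B		UV response regulator	csrB, yihA/csrC	2	TRUE	
ZraR		NtrC	type_A	AcP (ZraS)	Zn resistance-associated regulator	zraP/zraSzraR	2	TRUE	
YqhC		AraC	type_A		Glyoxal reductase regulator	yqhC/yqhDdkgA	2	TRUE	
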