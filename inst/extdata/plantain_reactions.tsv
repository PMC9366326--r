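# Reactions of the non-compartmented plantain central-metabolism network.
# Arrow convention: -> irreversible, <-> reversible. Nucleotide lumping:
# UTP/UDP are represented by ATP/ADP, so UDP-glucose formation consumes ATP
# and sucrose-phosphate synthase releases ADP. The FADH2 of the succinate
# step is lumped into NADH; oxidative phosphorylation uses a P/O of 2.5.
# Exchange reactions are one-sided: positive flux on an accumulation
# exchange (ACC_*) means net accumulation of that pool.
id	name	equation	kind	subsystem
EX_SUC_EXT	phloem sucrose supply	-> SUC_EXT	exchange	transport-in
EX_AA_EXT	phloem amino-acid supply	-> AA_EXT	exchange	transport-in
EX_NH4	ammonium supply	-> NH4	exchange	transport-in
EX_O2	oxygen uptake	-> O2	exchange	transport-in
EX_CO2	carbon dioxide release	CO2 ->	exchange	transport-in
EX_PI	phosphate supply	-> PI_EXT	exchange	transport-in
T_PI	phosphate uptake	PI_EXT -> PI	interconversion	transport-in
T_SUC	sucrose unloading	SUC_EXT -> SUC	interconversion	transport-in
T_AA	amino-acid unloading	AA_EXT -> AA	interconversion	transport-in
SUSY	sucrose synthase	SUC + ADP <-> UDPG + FRU	interconversion	sucrose cycle
INV	invertase	SUC -> GLC + FRU	interconversion	sucrose cycle
SPS	sucrose-phosphate synthase + phosphatase	UDPG + F6P -> SUC + ADP + PI	interconversion	sucrose cycle
UGP	UDP-glucose pyrophosphorylase	G1P + ATP <-> UDPG + PPI	interconversion	sucrose cycle
PPA	inorganic pyrophosphatase	PPI -> 2 PI	interconversion	sucrose cycle
HXK	hexokinase	GLC + ATP -> G6P + ADP	interconversion	glycolysis
FRK	fructokinase	FRU + ATP -> F6P + ADP	interconversion	glycolysis
PGI	phosphoglucose isomerase	G6P <-> F6P	interconversion	glycolysis
PGM	phosphoglucomutase	G6P <-> G1P	interconversion	starch
AGPASE	ADP-glucose pyrophosphorylase	G1P + ATP -> ADPG + PPI	interconversion	starch
SS	starch synthase	ADPG -> STARCH + ADP	interconversion	starch
STP	starch phosphorylase	STARCH + PI -> G1P	interconversion	starch
AMY	amylolytic starch breakdown	STARCH -> GLC	interconversion	starch
PFK	phosphofructokinase	F6P + ATP -> FBP + ADP	interconversion	glycolysis
FBA	aldolase + triose-phosphate isomerase	FBP <-> 2 TP	interconversion	glycolysis
GAPDH	GAPDH-enolase lump	TP + PI + ADP + NAD <-> PEP + ATP + NADH	interconversion	glycolysis
PK	pyruvate kinase	PEP + ADP -> PYR + ATP	interconversion	glycolysis
PEPC	PEP carboxylase	PEP + CO2 -> OAA + PI	interconversion	TCA
PDH	pyruvate dehydrogenase	PYR + NAD -> ACCOA + CO2 + NADH	interconversion	TCA
CS	citrate synthase	ACCOA + OAA -> CIT	interconversion	TCA
IDH	isocitrate dehydrogenase lump	CIT + NAD -> AKG + CO2 + NADH	interconversion	TCA
AKGMAL	2-oxoglutarate to malate lump	AKG + 2 NAD + ADP + PI -> MAL + CO2 + 2 NADH + ATP	interconversion	TCA
MDH	malate dehydrogenase	MAL + NAD <-> OAA + NADH	interconversion	TCA
ME	NADP-malic enzyme	MAL + NADP -> PYR + CO2 + NADPH	interconversion	TCA
G6PDH	oxidative pentose phosphate entry	G6P + 2 NADP -> RU5P + CO2 + 2 NADPH	interconversion	PPP
TKTA	non-oxidative PPP lump	3 RU5P <-> 2 F6P + TP	interconversion	PPP
TKTB	transketolase (E4P branch)	F6P + TP <-> E4P + RU5P	interconversion	PPP
NADHOX	respiratory chain (P/O 2.5)	NADH + 1/2 O2 + 5/2 ADP + 5/2 PI -> NAD + 5/2 ATP	interconversion	oxidative phosphorylation
THD	transhydrogenase-like NADPH/NADH exchange	NADPH + NAD <-> NADP + NADH	interconversion	oxidative phosphorylation
ATPM	maintenance ATPase	ATP -> ADP + PI	interconversion	oxidative phosphorylation
AASYN	amino-acid synthesis (glutamate lump)	AKG + NH4 + NADPH + ATP -> AA + NADP + ADP + PI	interconversion	biomass sink
PROTSYN	protein synthesis	AA + 4 ATP -> PROT + 4 ADP + 4 PI	interconversion	biomass sink
CWSYN	cell-wall glucan synthesis	UDPG -> CW + ADP	interconversion	biomass sink
PHENSYN	flavonoid synthesis lump	E4P + 2 PEP + 3 ACCOA + 5 ATP + 2 NADPH -> PHEN + CO2 + 5 ADP + 5 PI + 2 NADP	interconversion	polyphenol sink
ACC_SUC	sucrose accumulation	SUC <->	exchange	biomass sink
ACC_GLC	glucose accumulation	GLC <->	exchange	biomass sink
ACC_FRU	fructose accumulation	FRU <->	exchange	biomass sink
ACC_G6P	glucose 6-phosphate accumulation	G6P <->	exchange	biomass sink
ACC_G1P	glucose 1-phosphate accumulation	G1P <->	exchange	biomass sink
ACC_F6P	fructose 6-phosphate accumulation	F6P <->	exchange	biomass sink
ACC_STARCH	starch accumulation	STARCH <->	exchange	biomass sink
ACC_MAL	malate accumulation	MAL <->	exchange	biomass sink
ACC_AA	free amino-acid accumulation	AA <->	exchange	biomass sink
ACC_PROT	protein accumulation	PROT <->	exchange	biomass sink
ACC_CW	cell-wall accumulation	CW <->	exchange	biomass sink
ACC_PHEN	polyphenol accumulation	PHEN <->	exchange	polyphenol sink
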