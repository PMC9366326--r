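# Metabolites of the non-compartmented plantain central-metabolism network.
# role: internal = strictly balanced; accumulated = measured pool with an
# accumulation exchange; nutrient = boundary species (import/export).
# carbon_count is per lumped unit (starch/cell wall: glucosyl unit; protein:
# mean amino-acid residue; polyphenol: C15 flavonoid skeleton).
id	name	carbon_count	role
SUC_EXT	phloem sucrose	12	nutrient
AA_EXT	phloem amino acids	5	nutrient
NH4	ammonium	0	nutrient
O2	molecular oxygen	0	nutrient
CO2	carbon dioxide	1	nutrient
PI_EXT	external phosphate	0	nutrient
SUC	sucrose	12	accumulated
GLC	glucose	6	accumulated
FRU	fructose	6	accumulated
G6P	glucose 6-phosphate	6	accumulated
G1P	glucose 1-phosphate	6	accumulated
F6P	fructose 6-phosphate	6	accumulated
STARCH	starch (glucosyl unit)	6	accumulated
MAL	malate	4	accumulated
AA	free amino acids	5	accumulated
PROT	protein (residue unit)	5	accumulated
CW	cell wall (glucan unit)	6	accumulated
PHEN	polyphenols (C15 unit)	15	accumulated
UDPG	UDP-glucose	6	internal
ADPG	ADP-glucose	6	internal
FBP	fructose 1,6-bisphosphate	6	internal
TP	triose phosphates	3	internal
PEP	phosphoenolpyruvate	3	internal
PYR	pyruvate	3	internal
ACCOA	acetyl-CoA	2	internal
OAA	oxaloacetate	4	internal
CIT	citrate	6	internal
AKG	2-oxoglutarate	5	internal
RU5P	pentose 5-phosphates	5	internal
E4P	erythrose 4-phosphate	4	internal
ATP	ATP	0	internal
ADP	ADP	0	internal
PI	inorganic phosphate	0	internal
PPI	pyrophosphate	0	internal
NADH	NADH	0	internal
NAD	NAD+	0	internal
NADPH	NADPH	0	internal
NADP	NADP+	0	internal
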