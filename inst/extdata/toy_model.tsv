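# dynafba model
# metabolites
id	name	compartment	formula	mw	extracellular
GLC_e	D-glucose	e	C6H12O6	0.18	1
FRU_e	D-fructose	e	C6H12O6	0.18	1
NH3_e	ammonium	e	NH3	0.017	1
AAN_e	amino-acid nitrogen pool	e	C5H9NO4	0.147	1
ETH_e	ethanol	e	C2H6O	0.046	1
GLYC_e	glycerol	e	C3H8O3	0.092	1
ACE_e	acetate	e	C2H4O2	0.06	1
CO2_e	carbon dioxide (evolved)	e	CO2	0.044	1
O2_e	oxygen	e	O2	0.032	1
ERG_e	ergosterol	e	C28H44O	0.396	1
PI_e	phosphate	e	H3PO4	0.098	1
SO4_e	sulphate	e	H2SO4	0.098	1
H2_e	reducing equivalents (evolved)	e	H2	0.002	1
ACT_e	acetoin	e	C4H8O2	0.088	1
BTD_e	2,3-butanediol	e	C4H10O2	0.09	1
H2O_e	water	e	H2O	0.018	1
GLC_c	glucose	c	C6H12O6	0.18	0
FRU_c	fructose	c	C6H12O6	0.18	0
G6P_c	hexose 6-phosphate	c	C6H13O9P	0.26	0
T3P_c	triose 3-phosphate	c	C3H7O6P	0.17	0
G3P_c	glycerol 3-phosphate	c	C3H9O6P	0.172	0
PYR_c	pyruvate	c	C3H4O3	0.088	0
ACAL_c	acetaldehyde	c	C2H4O	0.044	0
ETH_c	ethanol	c	C2H6O	0.046	0
GLYC_c	glycerol	c	C3H8O3	0.092	0
ACE_c	acetate	c	C2H4O2	0.06	0
CO2_c	carbon dioxide	c	CO2	0.044	0
O2_c	oxygen	c	O2	0.032	0
NH3_c	ammonium	c	NH3	0.017	0
GLU_c	glutamate (amino-acid pool)	c	C5H9NO4	0.147	0
OAA_c	oxaloacetate	c	C4H4O5	0.132	0
AKG_c	2-oxoglutarate	c	C5H6O5	0.146	0
SUC_c	succinate	c	C4H6O4	0.118	0
MAL_c	malate	c	C4H6O5	0.134	0
FUM_c	fumarate	c	C4H4O4	0.116	0
COA_c	coenzyme A	c	C21H36N7O16P3S	0.767	0
ACCOA_c	acetyl-CoA	c	C23H38N7O17P3S	0.809	0
NAD_c	NAD (oxidised)	c	C21H26N7O14P2	0.662	0
NADH_c	NADH (carries H2)	c	C21H28N7O14P2	0.664	0
ATP_c	ATP	c	C10H16N5O13P3	0.507	0
ADP_c	ADP	c	C10H15N5O10P2	0.427	0
PI_c	phosphate	c	H3PO4	0.098	0
H2O_c	water	c	H2O	0.018	0
ERG_c	ergosterol	c	C28H44O	0.396	0
H2_c	reducing equivalents	c	H2	0.002	0
ACT_c	acetoin	c	C4H8O2	0.088	0
BTD_c	2,3-butanediol	c	C4H10O2	0.09	0
PROT_c	protein residue equivalent	c	C5H7NO3	0.129	0
CARB_c	storage carbohydrate residue	c	C6H10O5	0.162	0
LIP_c	lipid equivalent	c	C8H16O2	0.144	0
NUC_c	nucleic-acid equivalent	c	C5H10N2O3	0.146	0
# reactions
reaction_id	name	equation	lb	ub	genes	tags
EX_GLC	glucose exchange	GLC_e -> 	-inf	0		hexose_uptake,exchange
EX_FRU	fructose exchange	FRU_e -> 	-inf	0		hexose_uptake,exchange
EX_NH3	ammonium exchange	NH3_e -> 	-inf	0		nitrogen_uptake,exchange
EX_AAN	amino-acid exchange	AAN_e -> 	-inf	0		nitrogen_uptake,exchange
EX_ETH	ethanol exchange	ETH_e -> 	0	inf		exchange
EX_ACE	acetate exchange	ACE_e <-> 	-inf	inf		exchange
EX_CO2	CO2 exchange	CO2_e -> 	0	inf		exchange
EX_PI	phosphate exchange	PI_e <-> 	-inf	inf		exchange
EX_SO4	sulphate exchange	SO4_e <-> 	-inf	inf		exchange
EX_H2O	water exchange	H2O_e <-> 	-inf	inf		exchange
GLCt	hexose transporter (glc)	GLC_e -> GLC_c	0	inf	HXT1 or HXT2	
FRUt	hexose transporter (fru)	FRU_e -> FRU_c	0	inf	HXT1 or HXT2	
HXK	hexokinase	GLC_c + ATP_c -> G6P_c + ADP_c	0	inf	HXK2	
HXKF	fructokinase (lumped PGI)	FRU_c + ATP_c -> G6P_c + ADP_c	0	inf	HXK2	
PFK	upper glycolysis (PFK+aldolase)	G6P_c + ATP_c -> 2 T3P_c + ADP_c	0	inf	PFK1 and PFK2	
GAPD	lower glycolysis (GAPDH..PYK)	T3P_c + PI_c + 2 ADP_c + NAD_c -> PYR_c + 2 ATP_c + NADH_c + H2O_c	0	inf	TDH1 or TDH2 or TDH3	
PDC	pyruvate decarboxylase	PYR_c -> ACAL_c + CO2_c	0	inf	PDC1 or PDC5	
ADH	alcohol dehydrogenase	ACAL_c + NADH_c -> ETH_c + NAD_c	0	inf	ADH1	
ETHt	ethanol export	ETH_c -> ETH_e	0	inf		
CO2t	CO2 diffusion	CO2_c <-> CO2_e	-inf	inf		
PIt	phosphate transport	PI_e <-> PI_c	-inf	inf		
H2Ot	water diffusion	H2O_e <-> H2O_c	-inf	inf		
NH3t	ammonium transport	NH3_e -> NH3_c	0	inf	MEP1 or MEP2	
AANt	amino-acid uptake (glutamate pool)	AAN_e -> GLU_c	0	inf	GAP1	
GDH	glutamate dehydrogenase	AKG_c + NH3_c + NADH_c -> GLU_c + NAD_c + H2O_c	0	inf	GDH1	
PDH	pyruvate dehydrogenase (lumped bypass)	PYR_c + COA_c + NAD_c -> ACCOA_c + CO2_c + NADH_c	0	inf		
PYC	pyruvate carboxylase	PYR_c + CO2_c + ATP_c + H2O_c -> OAA_c + ADP_c + PI_c	0	inf	PYC1 or PYC2	
CSAKG	oxidative TCA branch (CS..IDH)	ACCOA_c + OAA_c + H2O_c + NAD_c -> AKG_c + CO2_c + NADH_c + COA_c	0	inf		
GPD	glycerol-3-phosphate dehydrogenase	T3P_c + NADH_c -> G3P_c + NAD_c	0	inf	GPD1 or GPD2	
GPP	glycerol-3-phosphatase	G3P_c + H2O_c -> GLYC_c + PI_c	0	inf	GPP1 or GPP2	
GLYCt	glycerol export	GLYC_c -> GLYC_e	0	inf	FPS1	
EX_GLYC	glycerol exchange	GLYC_e -> 	0	inf		exchange
ALD	acetaldehyde dehydrogenase	ACAL_c + NAD_c + H2O_c -> ACE_c + NADH_c	0	inf	ALD6	
ACEt	acetate transport	ACE_e <-> ACE_c	-inf	inf		
KGD	oxidative branch break (KGDH+SCS)	AKG_c + NAD_c + H2O_c <-> SUC_c + CO2_c + NADH_c	-inf	inf	KGD1 and LSC1	tca_oxidative_break
SDH	succinate dehydrogenase (NAD-lumped)	SUC_c + NAD_c <-> FUM_c + NADH_c	-inf	inf	SDH1 and SDH2	tca_oxidative_break
FUMS	fumarase	FUM_c + H2O_c <-> MAL_c	-inf	inf	FUM1	
MDH	malate dehydrogenase	MAL_c + NAD_c <-> OAA_c + NADH_c	-inf	inf	MDH1	
QNO	quinone-mediated NADH oxidation	NADH_c -> NAD_c + H2_c	0	inf	NDE1 or NDE2	quinone
H2t	reducing-equivalent evolution	H2_c -> H2_e	0	inf		
EX_H2	reducing-equivalent exchange	H2_e -> 	0	inf		exchange
O2t	oxygen diffusion	O2_e -> O2_c	0	inf		
EX_O2	oxygen exchange	O2_e -> 	-inf	0		oxygen_uptake,exchange
RESP	respiratory NADH oxidation	NADH_c + 0.5 O2_c + 2 ADP_c + 2 PI_c -> NAD_c + 2 ATP_c + 3 H2O_c	0	inf		
ERGt	sterol uptake	ERG_e -> ERG_c	0	inf	AUS1	
EX_ERG	ergosterol exchange	ERG_e -> 	0	0		sterol_uptake,exchange
ACTS	acetoin synthase (lumped)	2 ACAL_c -> ACT_c	0	inf	BDH2	
BTDS	butanediol dehydrogenase	ACT_c + NADH_c -> BTD_c + NAD_c	0	inf	BDH1	
ACTt	acetoin export	ACT_c -> ACT_e	0	inf		
BTDt	butanediol export	BTD_c -> BTD_e	0	inf		
EX_ACT	acetoin exchange	ACT_e -> 	0	inf		exchange
EX_BTD	butanediol exchange	BTD_e -> 	0	inf		exchange
PROTS	protein synthesis (lumped)	GLU_c + 2 ATP_c + H2O_c -> PROT_c + 2 ADP_c + 2 PI_c	0	inf		
CARBS	storage carbohydrate synthesis	G6P_c + ATP_c + H2O_c -> CARB_c + ADP_c + 2 PI_c	0	inf		
LIPS	lipid synthesis (lumped)	4 ACCOA_c + 6 NADH_c + 4 ATP_c + 2 H2O_c -> LIP_c + 4 COA_c + 6 NAD_c + 4 ADP_c + 4 PI_c	0	inf		
NUCS	nucleic-equivalent synthesis	GLU_c + NH3_c + ATP_c -> NUC_c + ADP_c + PI_c	0	inf		
ATPM	maintenance ATP hydrolysis	ATP_c + H2O_c -> ADP_c + PI_c	0	inf		maintenance_atp
BIOMASS	biomass (base composition)	3.527131783 PROT_c + 2.037037037 CARB_c + 0.4861111111 LIP_c + 0.9589041096 NUC_c + 0.01262626263 ERG_c + 70 ATP_c + 70 H2O_c -> 70 ADP_c + 70 PI_c	0	inf		biomass
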