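id	name	monoisotopic_mass	kegg_id	hmdb_id	pubchem_cid	chebi_id	cas	lipidmaps_id
DEMO001	glycine	75.0320284	C00037	HMDB0000123				
DEMO002	alanine	89.0476785	C00041	HMDB0000161				
DEMO003	serine	105.0425931	C00065	HMDB0000187				
DEMO004	proline	115.0633285	C00148	HMDB0000162				
DEMO005	valine	117.0789786	C00183	HMDB0000883				
DEMO006	threonine	119.0582432	C00188	HMDB0000167				
DEMO007	cysteine	121.0197492	C00097	HMDB0000574				
DEMO008	leucine	131.0946287	C00123	HMDB0000687				
DEMO009	isoleucine	131.0946287	C00407	HMDB0000172				
DEMO010	asparagine	132.0534921	C00152	HMDB0000168				
DEMO011	aspartate	133.0375077	C00049	HMDB0000191				
DEMO012	glutamine	146.0691422	C00064	HMDB0000641				
DEMO013	glutamate	147.0531578	C00025	HMDB0000148				
DEMO014	lysine	146.1055277	C00047	HMDB0000182				
DEMO015	methionine	149.0510493	C00073	HMDB0000696				
DEMO016	histidine	155.0694765	C00135	HMDB0000177				
DEMO017	phenylalanine	165.0789786	C00079	HMDB0000159				
DEMO018	arginine	174.1116757	C00062	HMDB0000517				
DEMO019	tyrosine	181.0738932	C00082	HMDB0000158				
DEMO020	tryptophan	204.0898776	C00078	HMDB0000929				
DEMO021	glucose	180.0633881	C00031	HMDB0000122				
DEMO022	fructose	180.0633881	C00095	HMDB0000660				
DEMO023	sucrose	342.1162115	C00089	HMDB0000258				
DEMO024	ribose	150.0528234	C00121	HMDB0000283				
DEMO025	myo-inositol	180.0633881	C00137	HMDB0000211				
DEMO026	lactate	90.0316941	C00186	HMDB0000190				
DEMO027	pyruvate	88.0160440	C00022	HMDB0000243				
DEMO028	citrate	192.0270026	C00158	HMDB0000094				
DEMO029	succinate	118.0266087	C00042	HMDB0000254				
DEMO030	fumarate	116.0109586	C00122	HMDB0000134				
DEMO031	malate	134.0215233	C00149	HMDB0000156				
DEMO032	alpha-ketoglutarate	146.0215233	C00026	HMDB0000208				
DEMO033	oxaloacetate	132.0058732	C00036	HMDB0000223				
DEMO034	creatine	131.0694765	C00300	HMDB0000064				
DEMO035	creatinine	113.0589119	C00791	HMDB0000562				
DEMO036	carnitine	161.1051934	C00318	HMDB0000062				
DEMO037	choline	103.0997140	C00114	HMDB0000097				
DEMO038	betaine	117.0789786	C00719	HMDB0000043				
DEMO039	taurine	125.0146638	C00245	HMDB0000251				
DEMO040	uric acid	168.0283400	C00366	HMDB0000289				
DEMO041	hypoxanthine	136.0385108	C00262	HMDB0000157				
DEMO042	xanthine	152.0334254	C00385	HMDB0000292				
DEMO043	uracil	112.0272774	C00106	HMDB0000300				
DEMO044	adenine	135.0544952	C00147	HMDB0000034				
DEMO045	adenosine	267.0967539	C00212	HMDB0000050				
DEMO046	inosine	268.0807695	C00294	HMDB0000195				
DEMO047	caffeine	194.0803756	C07481	HMDB0001847				
DEMO048	nicotinamide	122.0480128	C00153	HMDB0001406				
DEMO049	pantothenate	219.1106727	C00864	HMDB0000210				
DEMO050	citrulline	175.0956913	C00327	HMDB0000904				
DEMO051	ornithine	132.0898776	C00077	HMDB0000214				
DEMO052	glutathione	307.0838060	C00051	HMDB0000125				
DEMO053	palmitate	256.2402303	C00249	HMDB0000220				
DEMO054	stearate	284.2715304	C01530	HMDB0000827				
DEMO055	oleate	282.2558803	C00712	HMDB0000207				
DEMO056	cholesterol	386.3548661	C00187	HMDB0000067				
DEMO057	uridine	244.0695361	C00299	HMDB0000296				
DEMO058	guanosine	283.0916686	C00387	HMDB0000133				
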