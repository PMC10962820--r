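Majority protein IDs	Gene names	Unique peptides	Reverse	Potential contaminant	Only identified by site	LFQ intensity P001_B	LFQ intensity P001_F	LFQ intensity P002_B	LFQ intensity P002_F	LFQ intensity P003_B	LFQ intensity P003_F	LFQ intensity P004_B	LFQ intensity P004_F
SP00001	GENE1	7				14929275.9203872	10821571.429711	12746770.2353814	0	23301284.3568688	13459715.8100221	25974330.9093788	0
SP00002	GENE2	5				0	10470519.1897903	0	8864466.47079443	0	0	0	11315138.4036483
SP00003	GENE3	3				6531328.53075099	9330179.46862639	6027856.52905127	6795395.50999739	0	10951851.4671852	5021905.73333317	6072132.52438355
SP00004	GENE4	7				174470979.083289	150470143.952222	83890628.4222604	126961084.307087	135517546.158847	124044485.752082	173993220.668413	179957858.075915
SP00005	GENE5	5				13820825.2044625	0	8887867.9479579	14680648.2625778	10498157.9366856	21098137.5759507	8632162.10486817	0
SP00006	GENE6	5				59679468.4921636	66080427.6829328	55086614.8857065	62824399.954963	76310880.1047958	49429717.6710192	85811906.2775411	49753724.0784885
SP00007	GENE7	5				31171932.236759	24721383.8866931	20010831.791366	22036880.6173667	20285742.1482439	25712919.9562965	21082293.8182091	29826530.8403254
SP00008	GENE8	4				280704028.690411	334235488.986944	239180965.521157	247932736.424447	324113448.855099	268725571.201275	323810276.083346	279058967.812878
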