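virus	protein	host	group	tmd_length
HIV	gp41	animal	PM	30
Herpes Simplex	Env glycoprotein gH	animal	PM	28
Measles	Hemagglutinin	animal	PM	30
Sendai	Fusion Protein	animal	PM	25
Hepatitis C	E2 glycoprotein	animal	CME	17
Sindbis	E1 glycoprotein	animal	CME	5
Vesicular Stomatitis	Glycoprotein G	animal	CME	7
Semliki Forest	E1 glycoprotein	animal	CME	15
Equine Infectious Anemia	Outer membrane protein	animal	CME	10
Vaccinia	A21 protein	animal	MPE	8
Filamentous Influenza	Hemagglutinin	animal	MPE	27
Cytomegalovirus	Env Glycoprotein H	animal	MPE	20
Respiratory Syncytial virus A	F1 protein	animal	MPE	27
African Swine Fever	177L	animal	MPE	19
Ebola	Envelope Glycoprotein	animal	MPE	23
SV40	Agnoprotein	animal	CAME	10
Polyoma	Agnoprotein	animal	CAME	10
New Castle Disease	F1 protein	animal	CAME	25
Echovirus 1	Capsid protein	animal	CAME	10
Potato mop-top	TGBp2	plant	ER	20
Tomato-ringspot	X2	plant	ER	20
Tobacco-etch	6K2 protein	plant	ER	20
Potato Virus X	TGBp3	plant	ER	20
Maize Dwarf Mosaic	6K2	plant	ER	19
Turnip Mosaic	6K2	plant	ER	20
Flock house	Protein A	plant	Mitochondria	20
Carnation Italian Ringspot	Replication-associated protein 1	plant	Mitochondria	21
Pelargonium Flower Break	p27 protein	plant	Mitochondria	21
Tomato Bushy Stunt	p33	plant	Peroxisome	21
Cymbidium Ringspot	Movement protein	plant	Peroxisome	23
Cucumber Necrosis	p33	plant	Peroxisome	21
Turnip Yellow Mosaic	Methyl transferase	plant	Chloroplast	11
Cowpea chlorotic mottle	coat protein	plant	Chloroplast	15
Sonchus Yellow Net	M2 protein	plant	Nucleus	20
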