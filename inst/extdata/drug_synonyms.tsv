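verbatim	ingredient
dapagliflozin	dapagliflozin
famotidine	famotidine
mannitol	mannitol
tolvaptan	tolvaptan
norepinephrine	norepinephrine
norepinephrine bitartrate	norepinephrine
noradrenaline	norepinephrine
hydrocortisone	hydrocortisone
hydrocortisone sodium succinate	hydrocortisone
somatropin	somatropin
dexamethasone	dexamethasone
octreotide	octreotide
octreotide acetate	octreotide
lanreotide	lanreotide
pegvisomant	pegvisomant
amphotericin b	amphotericin b
amphotericin b liposomal	amphotericin b
tenofovir disoproxil	tenofovir disoproxil
tenofovir disoproxil fumarate	tenofovir disoproxil
piperacillin/tazobactam	piperacillin/tazobactam
emtricitabine/tenofovir disoproxil	emtricitabine/tenofovir disoproxil
voriconazole	voriconazole
foscarnet	foscarnet
foscarnet sodium	foscarnet
dolutegravir	dolutegravir
efavirenz	efavirenz
meropenem	meropenem
tigecycline	tigecycline
doxycycline	doxycycline
doxycycline hyclate	doxycycline
demeclocycline	demeclocycline
demeclocycline hydrochloride	demeclocycline
temozolomide	temozolomide
nivolumab	nivolumab
pembrolizumab	pembrolizumab
ipilimumab	ipilimumab
letrozole	letrozole
busulfan	busulfan
carboplatin	carboplatin
cyclophosphamide	cyclophosphamide
pemetrexed	pemetrexed
pemetrexed disodium	pemetrexed
cytarabine	cytarabine
azacitidine	azacitidine
etoposide	etoposide
ifosfamide	ifosfamide
vincristine	vincristine
vincristine sulfate	vincristine
lithium	lithium
lithium carbonate	lithium
lithium citrate	lithium
dexmedetomidine	dexmedetomidine
dexmedetomidine hcl	dexmedetomidine
dexmedetomidine hydrochloride	dexmedetomidine
quetiapine	quetiapine
quetiapine fumarate	quetiapine
levetiracetam	levetiracetam
olanzapine	olanzapine
valproic acid	valproic acid
valproate sodium	valproic acid
sodium valproate	valproic acid
clozapine	clozapine
risperidone	risperidone
aripiprazole	aripiprazole
sevoflurane	sevoflurane
paroxetine	paroxetine
paroxetine hydrochloride	paroxetine
ketamine	ketamine
ketamine hydrochloride	ketamine
phenytoin	phenytoin
phenytoin sodium	phenytoin
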