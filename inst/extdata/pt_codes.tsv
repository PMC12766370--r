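pt_cod	pt
10012599	Diabetes insipidus
10028813	Nausea
10019211	Headache
10012735	Diarrhoea
10047700	Vomiting
10016256	Fatigue
10013968	Dyspnoea
10037844	Rash
10037660	Pyrexia
10013573	Dizziness
10037087	Pruritus
10002034	Anaemia
10022437	Insomnia
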