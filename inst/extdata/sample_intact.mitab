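#ID(s) interactor A	ID(s) interactor B	Alt. ID(s) interactor A	Alt. ID(s) interactor B	Alias(es) interactor A	Alias(es) interactor B	Interaction detection method(s)	Publication 1st author(s)	Publication Identifier(s)	Taxid interactor A	Taxid interactor B	Interaction type(s)	Source database(s)	Interaction identifier(s)	Confidence value(s)
uniprotkb:P04637|intact:EBI-366083	uniprotkb:Q00987	-	-	-	-	-	-	-	-	-	-	-	-	intact-miscore:0.97
uniprotkb:P04637	uniprotkb:Q09472|intact:EBI-447295	-	-	-	-	-	-	-	-	-	-	-	-	author score:high|intact-miscore:0.89
uniprotkb:Q00987	uniprotkb:Q09472	-	-	-	-	-	-	-	-	-	-	-	-	intact-miscore:0.72
uniprotkb:P04637	uniprotkb:P06400	-	-	-	-	-	-	-	-	-	-	-	-	intact-miscore:0.66
uniprotkb:P06400	uniprotkb:Q09472	-	-	-	-	-	-	-	-	-	-	-	-	intact-miscore:0.58
uniprotkb:P04637	uniprotkb:P38936	-	-	-	-	-	-	-	-	-	-	-	-	intact-miscore:0.81
uniprotkb:P38936	uniprotkb:Q00987	-	-	-	-	-	-	-	-	-	-	-	-	intact-miscore:0.44
uniprotkb:Q00987	uniprotkb:P04637	-	-	-	-	-	-	-	-	-	-	-	-	intact-miscore:0.93
uniprotkb:P04637	uniprotkb:P04637	-	-	-	-	-	-	-	-	-	-	-	-	intact-miscore:0.35
uniprotkb:P42574	uniprotkb:P04637	-	-	-	-	-	-	-	-	-	-	-	-	intact-miscore:0.52
uniprotkb:P42574	uniprotkb:P06400	-	-	-	-	-	-	-	-	-	-	-	-	intact-miscore:0.47
uniprotkb:O15350	uniprotkb:P04637	-	-	-	-	-	-	-	-	-	-	-	-	intact-miscore:0.71
uniprotkb:O15350	uniprotkb:Q09472	-	-	-	-	-	-	-	-	-	-	-	-	author score:low|intact-miscore:0.63
uniprotkb:P63279	uniprotkb:P04637	-	-	-	-	-	-	-	-	-	-	-	-	intact-miscore:0.56
uniprotkb:P62993	uniprotkb:Q04206	-	-	-	-	-	-	-	-	-	-	-	-	intact-miscore:0.41
uniprotkb:Q04206	uniprotkb:P04637	-	-	-	-	-	-	-	-	-	-	-	-	intact-miscore:0.68
uniprotkb:P62993	uniprotkb:P63279	-	-	-	-	-	-	-	-	-	-	-	-	intact-miscore:0.38
uniprotkb:Q00987	uniprotkb:Q09472	-	-	-	-	-	-	-	-	-	-	-	-	intact-miscore:0.55
uniprotkb:P38936	uniprotkb:P06400	-	-	-	-	-	-	-	-	-	-	-	-	intact-miscore:0.49
uniprotkb:O15350	uniprotkb:Q00987	-	-	-	-	-	-	-	-	-	-	-	-	intact-miscore:0.33
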