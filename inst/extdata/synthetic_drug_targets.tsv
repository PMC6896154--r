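drug_id	drug_name	status	target_gene
D0001	Alphanib	approved	G0001
D0002	Betazole	approved	G0001
D0003	Gammacin	experimental	G0001
D0004	Deltamab	approved	G0002
D0005	Epsilonol	approved	G0002
D0006	Zetastat	other	G0003
D0007	Etaprazole	approved	G0003
D0008	Thetacillin	approved	G0004
D0009	Iotarelin	experimental	G0005
D0010	Kappaparib	approved	G0005
D0011	Lambdatinib	approved	G0005
D0012	Mucaine	approved	G0013
D0013	Nusertib	experimental	G0013
D0014	Ximofen	approved	G0015
D0002	Betazole	approved	G0015
D0015	Omicronate	approved	G0017
D0016	Pivastatin	approved	G0021
D0017	Rhosamide	experimental	G0050
D0018	Sigmaxicam	approved	G0101
D0019	Taumycin	approved	G0150
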