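coe	coe_members	species_id	occupied_ogus	area_fraction	cone	override	printed_label
Sky_islands	SPB,WLB	Kerkophorus_pumilio	SPB	0.20	Soutpansberg	none	narrow
Sky_islands	SPB,WLB	Ptilototheca_soutpansbergensis	SPB	0.15	Soutpansberg	none	narrow
Sky_islands	SPB,WLB	Kerkophorus_perfragilis	WLB	0.20	Wolkberg	none	narrow
Sky_islands	SPB,WLB	Sheldonia_wolkbergensis	WLB	0.20	Wolkberg	none	narrow
Extended_Maputaland	NMP,SMP,NMV,SMV	Chlamydephorus_watsoni	NMP,SMP,NMV	0.60		none	characteristic
Extended_Maputaland	NMP,SMP,NMV,SMV	Sheldonia_monsmaripi	NMV	0.10	Northern_Middleveld	none	narrow
Extended_Maputaland	NMP,SMP,NMV,SMV	Chlamydephorus_bruggeni	NMV	0.10	Northern_Middleveld	none	narrow
Extended_Maputaland	NMP,SMP,NMV,SMV	Microkerkus_sibaya	SMP	0.08		none	narrow
Natal	NMD,NCB,NGO	Natalina_inhluzana	NMD	0.15	Natal_Midlands	none	narrow
Natal	NMD,NCB,NGO	Kerkophorus_bicolor	NMD	0.12	Natal_Midlands	none	narrow
Natal	NMD,NCB,NGO	Microkerkus_burnupi	NMD	0.10	Natal_Midlands	none	narrow
Natal	NMD,NCB,NGO	Kerkophorus_ampliatus	NCB,NGO	0.25	Natal_Coastal_Belt_Ngoye	none	narrow
Natal	NMD,NCB,NGO	Kerkophorus_melvilli	NCB,NGO	0.22	Natal_Coastal_Belt_Ngoye	none	narrow
Natal	NMD,NCB,NGO	Kerkophorus_russofulgens	NCB,NGO	0.20	Natal_Coastal_Belt_Ngoye	none	narrow
Extended_Pondoland	PND,STR	Natalina_beyrichi	PND,STR	0.80		none	characteristic
Extended_Pondoland	PND,STR	Kerkophorus_vitalis	PND,STR	0.75		none	characteristic
Extended_Pondoland	PND,STR	Microkerkus_pondoensis	PND,STR	0.30		none	narrow
Extended_Pondoland	PND,STR	Kerkophorus_puzeyi	PND,STR	0.35		none	narrow
Extended_Pondoland	PND,STR	Kerkophorus_terrestris	PND,STR	0.40		none	narrow
Extended_Pondoland	PND,STR	Kerkophorus_scrobicolus	PND	0.20		none	narrow
Extended_Pondoland	PND,STR	Sheldonia_fingolandensis	STR	0.15		none	narrow
Albany_Knysna	ACB,KNY	Afrorhytida_kraussi	KNY	0.55		not_narrow	characteristic
Albany_Knysna	ACB,KNY	Sheldonia_phytostylus	KNY	0.55		not_narrow	characteristic
Albany_Knysna	ACB,KNY	Sheldonia_aloicola	ACB,KNY	0.70		none	characteristic
Albany_Knysna	ACB,KNY	Sheldonia_hudsoniae	ACB,KNY	0.65		none	characteristic
Albany_Knysna	ACB,KNY	Kerkophorus_knysnaensis	KNY	0.52		none	characteristic
Albany_Knysna	ACB,KNY	Chlamydephorus_parva	ACB	0.20		none	narrow
Albany_Knysna	ACB,KNY	Capitina_schaerfiae	KNY	0.10	Knysna	none	narrow
Albany_Knysna	ACB,KNY	Nata_aequiplicata	KNY	0.12	Knysna	none	narrow
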