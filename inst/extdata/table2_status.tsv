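family	species_id	mpa_hotspot	mpa_knysna	greater_mpa	sea_dominion	study_area	note
Bothriembryontidae	Prestonella_bowkeri	0	0	0	1	1	
Bothriembryontidae	Prestonella_nuptialis	1	0	1	1	1	narrow_fn
Rhytididae	Chlamydephorus_bruggeni	1	1	1	1	1	narrow_fn
Rhytididae	Chlamydephorus_burnupi	0	0	1	1	1	amb:mpa_hotspot,mpa_knysna
Rhytididae	Chlamydephorus_dimidius	1	1	1	1	1	
Rhytididae	Chlamydephorus_gibbonsi	1	1	1	1	1	
Rhytididae	Chlamydephorus_lawrencei	0	0	1	1	1	
Rhytididae	Chlamydephorus_parva	1	1	1	1	1	narrow_fn
Rhytididae	Chlamydephorus_purcelli	0	0	0	0	1	
Rhytididae	Chlamydephorus_sexangulus	0	1	1	1	1	
Rhytididae	Chlamydephorus_watsoni	1	1	1	1	1	
Rhytididae	Afrorhytida_burseyae	1	0	1	1	1	amb:mpa_knysna
Rhytididae	Afrorhytida_knysnaensis	1	0	1	1	1	
Rhytididae	Afrorhytida_kraussi	0	1	1	1	1	
Rhytididae	Afrorhytida_trimeni	1	1	1	1	1	narrow_fn
Rhytididae	Capitina_calcicola	0	0	0	0	1	
Rhytididae	Capitina_schaerfiae	0	1	1	1	1	narrow_fn
Rhytididae	Nata_aequiplicata	1	1	1	1	1	narrow_fn
Rhytididae	Nata_dumeticola	0	0	0	0	0	near_endemic:study_area
Rhytididae	Nata_tarachodes	0	0	0	0	1	
Rhytididae	Nata_vernicosa-erugata	0	0	0	0	1	
Rhytididae	Nata_watsoni	1	0	1	1	1	
Rhytididae	Natalina_beyrichi	1	1	1	1	1	
Rhytididae	Natalina_cafra	1	1	1	1	1	
Rhytididae	Natalina_inhluzana	1	1	1	1	1	narrow_fn
Rhytididae	Natalina_quekettiana	0	0	1	1	1	amb:mpa_hotspot,mpa_knysna
Rhytididae	Natalina_reenenensis	1	1	1	1	1	narrow_fn
Rhytididae	Natalina_wesseliana	0	0	0	0	1	
Rhytididae	Natella_viridescens	0	0	0	1	1	amb:mpa_hotspot,mpa_knysna,greater_mpa
Urocyclidae	Kerkophorus_ampliatus	1	1	1	1	1	narrow_fn
Urocyclidae	Kerkophorus_bicolor	0	1	1	1	1	narrow_fn
Urocyclidae	Kerkophorus_cingulatus	0	1	1	1	1	
Urocyclidae	Kerkophorus_corneus	0	0	1	1	1	amb:mpa_knysna
Urocyclidae	Kerkophorus_inunctus	1	1	1	1	1	
Urocyclidae	Kerkophorus_knysnaensis	0	1	1	1	1	
Urocyclidae	Kerkophorus_melvilli	1	1	1	1	1	narrow_fn
Urocyclidae	Kerkophorus_perfragilis	0	0	1	1	1	NE;amb:mpa_knysna
Urocyclidae	Kerkophorus_perlevis	0	1	1	1	1	
Urocyclidae	Kerkophorus_piperatus-vittarubra	0	0	1	1	1	amb:mpa_knysna
Urocyclidae	Kerkophorus_poeppigii	0	0	0	1	1	amb:mpa_hotspot,mpa_knysna,greater_mpa
Urocyclidae	Kerkophorus_pumilio	0	0	1	1	1	narrow_fn;amb:mpa_knysna
Urocyclidae	Kerkophorus_puzeyi	1	1	1	1	1	narrow_fn
Urocyclidae	Kerkophorus_russofulgens	1	1	1	1	1	narrow_fn
Urocyclidae	Kerkophorus_scrobicolus	1	1	1	1	1	narrow_fn
Urocyclidae	Kerkophorus_terrestris	1	1	1	1	1	narrow_fn
Urocyclidae	Kerkophorus_vandenbroeckii	0	0	1	1	1	narrow_fn;amb:mpa_knysna
Urocyclidae	Kerkophorus_vitalis	1	1	1	1	1	
Urocyclidae	Kerkophorus_zonamydrus	0	1	1	1	1	
Urocyclidae	Microkerkus_arnotti	0	0	0	0	1	
Urocyclidae	Microkerkus_burnupi	0	1	1	1	1	narrow_fn
Urocyclidae	Microkerkus_chrysoprasinus	0	0	1	1	1	amb:mpa_hotspot,mpa_knysna
Urocyclidae	Microkerkus_fuscicolor	0	0	0	1	1	amb:mpa_hotspot,mpa_knysna,greater_mpa
Urocyclidae	Microkerkus_leucospira	1	1	1	1	1	
Urocyclidae	Microkerkus_maseruensis	0	0	1	1	1	narrow_fn;amb:mpa_hotspot,mpa_knysna
Urocyclidae	Microkerkus_pondoensis	1	1	1	1	1	narrow_fn
Urocyclidae	Microkerkus_sibaya	1	1	1	1	1	narrow_fn
Urocyclidae	Microkerkus_symmetricus	0	0	0	1	1	amb:mpa_hotspot,mpa_knysna,greater_mpa
Urocyclidae	Microkerkus_transvaalensis	0	0	1	1	1	amb:mpa_knysna
Urocyclidae	Ptilototheca_soutpansbergensis	0	0	1	1	1	narrow_fn;amb:mpa_knysna
Urocyclidae	Selatodryas_luteosoma-roseosoma	1	0	1	1	1	narrow_fn;amb:mpa_knysna
Urocyclidae	Sheldonia_aloicola	1	1	1	1	1	
Urocyclidae	Sheldonia_asthenes	0	0	1	1	1	
Urocyclidae	Sheldonia_caledonensis	0	0	0	0	1	
Urocyclidae	Sheldonia_capsula	0	0	0	0	1	
Urocyclidae	Sheldonia_cotyledonis	0	0	0	0	1	
Urocyclidae	Sheldonia_crawfordi	0	0	1	1	1	
Urocyclidae	Sheldonia_fingolandensis	1	1	1	1	1	narrow_fn
Urocyclidae	Sheldonia_hudsoniae	0	1	1	1	1	
Urocyclidae	Sheldonia_monsmaripi	1	1	1	1	1	narrow_fn
Urocyclidae	Sheldonia_natalensis	0	1	1	1	1	
Urocyclidae	Sheldonia_phytostylus	0	1	1	1	1	
Urocyclidae	Sheldonia_trotteriana	0	0	0	1	1	
Urocyclidae	Sheldonia_wolkbergensis	0	0	1	1	1	narrow_fn;amb:mpa_knysna
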