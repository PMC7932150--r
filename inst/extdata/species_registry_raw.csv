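species_id,name,genus,family
Prestonella_bowkeri,Prestonella bowkeri,Prestonella,Bothriembryontidae
Prestonella_nuptialis,Prestonella nuptialis,Prestonella,Bothriembryontidae
Prestonella_quadingensis,Prestonella quadingensis,Prestonella,Bothriembryontidae
Chlamydephorus_bruggeni,Chlamydephorus bruggeni,Chlamydephorus,Rhytididae
Chlamydephorus_burnupi,Chlamydephorus burnupi,Chlamydephorus,Rhytididae
Chlamydephorus_dimidius,Chlamydephorus dimidius,Chlamydephorus,Rhytididae
Chlamydephorus_gibbonsi,Chlamydephorus gibbonsi,Chlamydephorus,Rhytididae
Chlamydephorus_lawrencei,Chlamydephorus lawrencei,Chlamydephorus,Rhytididae
Chlamydephorus_parva,Chlamydephorus parva,Chlamydephorus,Rhytididae
Chlamydephorus_purcelli,Chlamydephorus purcelli,Chlamydephorus,Rhytididae
Chlamydephorus_sexangulus,Chlamydephorus sexangulus,Chlamydephorus,Rhytididae
Chlamydephorus_watsoni,Chlamydephorus watsoni,Chlamydephorus,Rhytididae
Afrorhytida_burseyae,Afrorhytida burseyae,Afrorhytida,Rhytididae
Afrorhytida_knysnaensis,Afrorhytida knysnaensis,Afrorhytida,Rhytididae
Afrorhytida_kraussi,Afrorhytida kraussi,Afrorhytida,Rhytididae
Afrorhytida_trimeni,Afrorhytida trimeni,Afrorhytida,Rhytididae
Capitina_calcicola,Capitina calcicola,Capitina,Rhytididae
Capitina_schaerfiae,Capitina schaerfiae,Capitina,Rhytididae
Nata_aequiplicata,Nata aequiplicata,Nata,Rhytididae
Nata_dumeticola,Nata dumeticola,Nata,Rhytididae
Nata_erugata,Nata erugata,Nata,Rhytididae
Nata_tarachodes,Nata tarachodes,Nata,Rhytididae
Nata_vernicosa,Nata vernicosa,Nata,Rhytididae
Nata_watsoni,Nata watsoni,Nata,Rhytididae
Natalina_beyrichi,Natalina beyrichi,Natalina,Rhytididae
Natalina_cafra,Natalina cafra,Natalina,Rhytididae
Natalina_inhluzana,Natalina inhluzana,Natalina,Rhytididae
Natalina_quekettiana,Natalina quekettiana,Natalina,Rhytididae
Natalina_reenenensis,Natalina reenenensis,Natalina,Rhytididae
Natalina_wesseliana,Natalina wesseliana,Natalina,Rhytididae
Natella_viridescens,Natella viridescens,Natella,Rhytididae
Kerkophorus_ampliatus,Kerkophorus ampliatus,Kerkophorus,Urocyclidae
Kerkophorus_bicolor,Kerkophorus bicolor,Kerkophorus,Urocyclidae
Kerkophorus_cingulatus,Kerkophorus cingulatus,Kerkophorus,Urocyclidae
Kerkophorus_corneus,Kerkophorus corneus,Kerkophorus,Urocyclidae
Kerkophorus_inunctus,Kerkophorus inunctus,Kerkophorus,Urocyclidae
Kerkophorus_knysnaensis,Kerkophorus knysnaensis,Kerkophorus,Urocyclidae
Kerkophorus_melvilli,Kerkophorus melvilli,Kerkophorus,Urocyclidae
Kerkophorus_perfragilis,Kerkophorus perfragilis,Kerkophorus,Urocyclidae
Kerkophorus_perlevis,Kerkophorus perlevis,Kerkophorus,Urocyclidae
Kerkophorus_phaedimus,Kerkophorus phaedimus,Kerkophorus,Urocyclidae
Kerkophorus_piperatus,Kerkophorus piperatus,Kerkophorus,Urocyclidae
Kerkophorus_poeppigii,Kerkophorus poeppigii,Kerkophorus,Urocyclidae
Kerkophorus_pumilio,Kerkophorus pumilio,Kerkophorus,Urocyclidae
Kerkophorus_puzeyi,Kerkophorus puzeyi,Kerkophorus,Urocyclidae
Kerkophorus_russofulgens,Kerkophorus russofulgens,Kerkophorus,Urocyclidae
Kerkophorus_scrobicolus,Kerkophorus scrobicolus,Kerkophorus,Urocyclidae
Kerkophorus_terrestris,Kerkophorus terrestris,Kerkophorus,Urocyclidae
Kerkophorus_vandenbroeckii,Kerkophorus vandenbroeckii,Kerkophorus,Urocyclidae
Kerkophorus_vitalis,Kerkophorus vitalis,Kerkophorus,Urocyclidae
Kerkophorus_vittarubra,Kerkophorus vittarubra,Kerkophorus,Urocyclidae
Kerkophorus_zonamydrus,Kerkophorus zonamydrus,Kerkophorus,Urocyclidae
Microkerkus_arnotti,Microkerkus arnotti,Microkerkus,Urocyclidae
Microkerkus_burnupi,Microkerkus burnupi,Microkerkus,Urocyclidae
Microkerkus_chrysoprasinus,Microkerkus chrysoprasinus,Microkerkus,Urocyclidae
Microkerkus_fuscicolor,Microkerkus fuscicolor,Microkerkus,Urocyclidae
Microkerkus_leucospira,Microkerkus leucospira,Microkerkus,Urocyclidae
Microkerkus_maseruensis,Microkerkus maseruensis,Microkerkus,Urocyclidae
Microkerkus_pondoensis,Microkerkus pondoensis,Microkerkus,Urocyclidae
Microkerkus_sibaya,Microkerkus sibaya,Microkerkus,Urocyclidae
Microkerkus_symmetricus,Microkerkus symmetricus,Microkerkus,Urocyclidae
Microkerkus_transvaalensis,Microkerkus transvaalensis,Microkerkus,Urocyclidae
Ptilototheca_soutpansbergensis,Ptilototheca soutpansbergensis,Ptilototheca,Urocyclidae
Selatodryas_luteosoma,Selatodryas luteosoma,Selatodryas,Urocyclidae
Selatodryas_roseosoma,Selatodryas roseosoma,Selatodryas,Urocyclidae
Sheldonia_aloicola,Sheldonia aloicola,Sheldonia,Urocyclidae
Sheldonia_asthenes,Sheldonia asthenes,Sheldonia,Urocyclidae
Sheldonia_caledonensis,Sheldonia caledonensis,Sheldonia,Urocyclidae
Sheldonia_capsula,Sheldonia capsula,Sheldonia,Urocyclidae
Sheldonia_cotyledonis,Sheldonia cotyledonis,Sheldonia,Urocyclidae
Sheldonia_crawfordi,Sheldonia crawfordi,Sheldonia,Urocyclidae
Sheldonia_fingolandensis,Sheldonia fingolandensis,Sheldonia,Urocyclidae
Sheldonia_hewitti,Sheldonia hewitti,Sheldonia,Urocyclidae
Sheldonia_hudsoniae,Sheldonia hudsoniae,Sheldonia,Urocyclidae
Sheldonia_monsmaripi,Sheldonia monsmaripi,Sheldonia,Urocyclidae
Sheldonia_natalensis,Sheldonia natalensis,Sheldonia,Urocyclidae
Sheldonia_phytostylus,Sheldonia phytostylus,Sheldonia,Urocyclidae
Sheldonia_trotteriana,Sheldonia trotteriana,Sheldonia,Urocyclidae
Sheldonia_wolkbergensis,Sheldonia wolkbergensis,Sheldonia,Urocyclidae
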