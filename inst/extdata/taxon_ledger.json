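[
  {"kind": "exclude", "name": "Prestonella_quadingensis",
   "reason": "no distribution data beyond the type locality"},
  {"kind": "merge_complex",
   "members": ["Nata_erugata", "Nata_vernicosa"],
   "new_name": "Nata_vernicosa-erugata",
   "reason": "species complex with unresolved distribution records"},
  {"kind": "synonymise", "junior": "Kerkophorus_phaedimus",
   "senior": "Kerkophorus_corneus"},
  {"kind": "merge_complex",
   "members": ["Kerkophorus_piperatus", "Kerkophorus_vittarubra"],
   "new_name": "Kerkophorus_piperatus-vittarubra",
   "reason": "morphologically inseparable at some localities"},
  {"kind": "merge_complex",
   "members": ["Selatodryas_luteosoma", "Selatodryas_roseosoma"],
   "new_name": "Selatodryas_luteosoma-roseosoma",
   "reason": "reliable identification requires dissection"},
  {"kind": "synonymise", "junior": "Sheldonia_hewitti",
   "senior": "Sheldonia_aloicola"}
]
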