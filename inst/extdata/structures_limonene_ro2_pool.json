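{
  "version": 1,
  "description": "Representative limonene-ozonolysis RO2 radicals (one per oxygen number) used for dimer precursor-pair inference and campaign simulation. The O6 radical is encoded as an acylperoxy radical, consistent with the asymmetric RO-OR cleavage of the O12 dimer.",
  "structures": [
    {"id": "lim-O4", "species": "RO2_radical", "formula": "C10H15O4*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": false, "has_peroxy_acid": false, "has_carbonyl": true,
     "note": "first-generation ring-opened peroxy radical"},
    {"id": "lim-O6", "species": "RO2_radical", "formula": "C10H15O6*",
     "ro2_site_class": "acylperoxy", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": false, "has_carbonyl": true,
     "note": "acylperoxy radical from the aldehydic H-shift; cannot act as H-donor in RO-OR cleavage"},
    {"id": "lim-O8", "species": "RO2_radical", "formula": "C10H15O8*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "channels": ["R-O2", "R-HNO3-OH", "R-H2O", "R-CO2", "R-OHelim"],
     "note": "representative surviving O8 structure (A/B 1, 2 or A7 feature set)"},
    {"id": "lim-O10", "species": "RO2_radical", "formula": "C10H15O10*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "radical_near_peroxy": true,
     "channels": ["R-O2", "R-OHelim", "R-HO2", "R-CHO3"],
     "note": "representative surviving O10 structure"}
  ]
}
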