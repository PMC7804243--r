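{
  "version": 1,
  "description": "Candidate C10H15O8 peroxy-radical isomers from the two limonene ozonolysis routes (A and B). Feature flags encode the structural traits that gate fragmentation channels: site class of the peroxy radical, whether the carbon alpha to the radical (after O2 loss) is quaternary, and the functional groups present. The channels list records the fragmentation channels this family's spectra exhibit (O2 loss, combined HNO3+OH loss, H2O loss, CO2 loss, OH elimination).",
  "structures": [
    {"id": "A1", "species": "RO2_radical", "formula": "C10H15O8*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "channels": ["R-O2", "R-HNO3-OH", "R-H2O", "R-CO2", "R-OHelim"],
     "note": "A-route 1,4 aldehydic H-shift product; secondary peroxy radical with hydroperoxide and peroxy-acid groups"},
    {"id": "A2", "species": "RO2_radical", "formula": "C10H15O8*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "channels": ["R-O2", "R-HNO3-OH", "R-H2O", "R-CO2", "R-OHelim"],
     "note": "A-route 1,6 H-shift product; secondary peroxy radical, non-quaternary alpha carbon"},
    {"id": "A3", "species": "RO2_radical", "formula": "C10H15O8*",
     "ro2_site_class": "tertiary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "channels": ["R-O2", "R-HNO3-OH", "R-H2O", "R-CO2", "R-OHelim"],
     "note": "tertiary alkylperoxy radical: OH elimination with ketone formation is blocked"},
    {"id": "A4", "species": "RO2_radical", "formula": "C10H15O8*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": true,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "channels": ["R-O2", "R-HNO3-OH", "R-H2O", "R-CO2", "R-OHelim"],
     "note": "quaternary carbon adjacent to the alkyl radical: combined HNO3+OH loss blocked"},
    {"id": "A5", "species": "RO2_radical", "formula": "C10H15O8*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": true,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "channels": ["R-O2", "R-HNO3-OH", "R-H2O", "R-CO2", "R-OHelim"],
     "note": "quaternary alpha carbon"},
    {"id": "A6", "species": "RO2_radical", "formula": "C10H15O8*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": true,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "channels": ["R-O2", "R-HNO3-OH", "R-H2O", "R-CO2", "R-OHelim"],
     "note": "quaternary alpha carbon"},
    {"id": "A7", "species": "RO2_radical", "formula": "C10H15O8*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "channels": ["R-O2", "R-HNO3-OH", "R-H2O", "R-CO2", "R-OHelim"],
     "note": "A-route 1,7 H-shift product; accommodates every observed channel"},
    {"id": "B1", "species": "RO2_radical", "formula": "C10H15O8*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "channels": ["R-O2", "R-HNO3-OH", "R-H2O", "R-CO2", "R-OHelim"],
     "note": "B-route 1,4 H-shift product"},
    {"id": "B2", "species": "RO2_radical", "formula": "C10H15O8*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "channels": ["R-O2", "R-HNO3-OH", "R-H2O", "R-CO2", "R-OHelim"],
     "note": "B-route 1,6 H-shift product"},
    {"id": "B3", "species": "RO2_radical", "formula": "C10H15O8*",
     "ro2_site_class": "tertiary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "scramble_sites": 1,
     "scrb_overrides": [{"ro2_site_class": "secondary"}],
     "channels": ["R-O2", "R-HNO3-OH", "R-H2O", "R-CO2", "R-OHelim"],
     "note": "tertiary alkylperoxy radical; a hydroperoxide H-scramble relocates the radical to a secondary site"},
    {"id": "B4", "species": "RO2_radical", "formula": "C10H15O8*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": true,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "channels": ["R-O2", "R-HNO3-OH", "R-H2O", "R-CO2", "R-OHelim"],
     "note": "quaternary alpha carbon"},
    {"id": "B5", "species": "RO2_radical", "formula": "C10H15O8*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": true,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "channels": ["R-O2", "R-HNO3-OH", "R-H2O", "R-CO2", "R-OHelim"],
     "note": "quaternary alpha carbon"},
    {"id": "B6", "species": "RO2_radical", "formula": "C10H15O8*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": true,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "channels": ["R-O2", "R-HNO3-OH", "R-H2O", "R-CO2", "R-OHelim"],
     "note": "quaternary alpha carbon"},
    {"id": "B7", "species": "RO2_radical", "formula": "C10H15O8*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": true,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "scramble_sites": 1,
     "scrb_overrides": [{"alpha_carbon_quaternary": false}],
     "channels": ["R-O2", "R-HNO3-OH", "R-H2O", "R-CO2", "R-OHelim"],
     "note": "quaternary alpha carbon; its single H-scramble variant has the same feature set as A7"}
  ]
}
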