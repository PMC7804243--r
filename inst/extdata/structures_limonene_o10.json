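{
  "version": 1,
  "description": "Candidate C10H15O10 peroxy-radical isomers derived from the surviving O8 structures by a further H-shift plus O2 addition. Naming: parent O8 id, dash, derivative index. Channels observed for this family: O2 loss, OH elimination, HO2 elimination, and CHO3 loss via radical recombination after O2 elimination.",
  "structures": [
    {"id": "A1-1", "species": "RO2_radical", "formula": "C10H15O10*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "radical_near_peroxy": true,
     "channels": ["R-O2", "R-OHelim", "R-HO2", "R-CHO3"],
     "note": "1,5 H-shift from a saturated carbon; secondary peroxy radical next to a peroxy group"},
    {"id": "A1-2", "species": "RO2_radical", "formula": "C10H15O10*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "radical_near_peroxy": false,
     "channels": ["R-O2", "R-OHelim", "R-HO2", "R-CHO3"],
     "note": "secondary peroxy radical remote from any peroxy group: CHO3 radical recombination blocked"},
    {"id": "A2-1", "species": "RO2_radical", "formula": "C10H15O10*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "radical_near_peroxy": true,
     "channels": ["R-O2", "R-OHelim", "R-HO2", "R-CHO3"],
     "note": "1,6 H-shift from a saturated carbon"},
    {"id": "A2-5", "species": "RO2_radical", "formula": "C10H15O10*",
     "ro2_site_class": "tertiary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "radical_near_peroxy": true,
     "channels": ["R-O2", "R-OHelim", "R-HO2", "R-CHO3"],
     "note": "tertiary alkylperoxy radical: OH elimination blocked"},
    {"id": "A1-6", "species": "RO2_radical", "formula": "C10H15O10*",
     "ro2_site_class": "tertiary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "radical_near_peroxy": true,
     "channels": ["R-O2", "R-OHelim", "R-HO2", "R-CHO3"],
     "note": "tertiary alkylperoxy radical"},
    {"id": "A7-1", "species": "RO2_radical", "formula": "C10H15O10*",
     "ro2_site_class": "tertiary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "radical_near_peroxy": true,
     "channels": ["R-O2", "R-OHelim", "R-HO2", "R-CHO3"],
     "note": "tertiary alkylperoxy radical"},
    {"id": "A7-2", "species": "RO2_radical", "formula": "C10H15O10*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "radical_near_peroxy": true,
     "channels": ["R-O2", "R-OHelim", "R-HO2", "R-CHO3"],
     "note": "1,5 H-shift from a saturated carbon; accommodates every observed channel"},
    {"id": "A7-5", "species": "RO2_radical", "formula": "C10H15O10*",
     "ro2_site_class": "tertiary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "radical_near_peroxy": true,
     "channels": ["R-O2", "R-OHelim", "R-HO2", "R-CHO3"],
     "note": "tertiary alkylperoxy radical"},
    {"id": "B1-1", "species": "RO2_radical", "formula": "C10H15O10*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "radical_near_peroxy": true,
     "channels": ["R-O2", "R-OHelim", "R-HO2", "R-CHO3"],
     "note": "1,5 H-shift from a saturated carbon"},
    {"id": "B1-2", "species": "RO2_radical", "formula": "C10H15O10*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "radical_near_peroxy": false,
     "channels": ["R-O2", "R-OHelim", "R-HO2", "R-CHO3"],
     "note": "secondary peroxy radical remote from any peroxy group: CHO3 radical recombination blocked"},
    {"id": "B1-6", "species": "RO2_radical", "formula": "C10H15O10*",
     "ro2_site_class": "tertiary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "radical_near_peroxy": true,
     "channels": ["R-O2", "R-OHelim", "R-HO2", "R-CHO3"],
     "note": "tertiary alkylperoxy radical"},
    {"id": "B2-1", "species": "RO2_radical", "formula": "C10H15O10*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "radical_near_peroxy": true,
     "channels": ["R-O2", "R-OHelim", "R-HO2", "R-CHO3"],
     "note": "1,6 H-shift from a saturated carbon"},
    {"id": "B2-6", "species": "RO2_radical", "formula": "C10H15O10*",
     "ro2_site_class": "tertiary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "radical_near_peroxy": true,
     "channels": ["R-O2", "R-OHelim", "R-HO2", "R-CHO3"],
     "note": "tertiary alkylperoxy radical"}
  ]
}
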