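{
  "version": 1,
  "description": "Representative a-pinene-ozonolysis RO2 radicals. The gem-dimethyl quaternary carbon of the pinene skeleton enables the CH3O2 and C3H6O losses that are absent from limonene spectra; the O6 radical is not acylperoxy here, and dimer evidence points to O4 + O10 precursor pairs.",
  "structures": [
    {"id": "ap-O4", "species": "RO2_radical", "formula": "C10H15O4*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": false, "has_peroxy_acid": false, "has_carbonyl": true,
     "gem_dimethyl_quaternary": true,
     "note": "first-generation peroxy radical retaining the gem-dimethyl motif"},
    {"id": "ap-O6", "species": "RO2_radical", "formula": "C10H15O6*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": false, "has_carbonyl": true,
     "gem_dimethyl_quaternary": true,
     "note": "non-acyl secondary peroxy radical"},
    {"id": "ap-O8", "species": "RO2_radical", "formula": "C10H15O8*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "gem_dimethyl_quaternary": true,
     "channels": ["R-O2", "R-CO2", "R-H2O", "R-CH3O2", "R-C3H6O"],
     "note": "O8 peroxy radical showing the pinene-specific CH3O2 and C3H6O losses"},
    {"id": "ap-O10", "species": "RO2_radical", "formula": "C10H15O10*",
     "ro2_site_class": "secondary", "alpha_carbon_quaternary": false,
     "has_hydroperoxide": true, "has_peroxy_acid": true, "has_carbonyl": true,
     "radical_near_peroxy": true, "gem_dimethyl_quaternary": true,
     "note": "highly oxidized peroxy radical; key dimer precursor together with ap-O4"}
  ]
}
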