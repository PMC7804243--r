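{
  "version": 1,
  "rules": [
    {
      "id": "R-O2",
      "loss": "O2",
      "applies_to": [
        "RO2_radical"
      ],
      "predicate": "has_peroxy_site",
      "anchor": "loss of the peroxy functional group as O2; available to every peroxy radical"
    },
    {
      "id": "R-HNO3",
      "loss": "HNO3",
      "applies_to": [
        "closed_shell",
        "dimer"
      ],
      "predicate": "always",
      "anchor": "declustering of the nitrate adduct as nitric acid; characteristic of closed-shell molecules and rare for RO2 radicals"
    },
    {
      "id": "R-HNO3-OH",
      "loss": "H2NO4",
      "applies_to": [
        "RO2_radical"
      ],
      "predicate": "alpha_not_quaternary",
      "anchor": "combined HNO3 and OH loss after O2 elimination; needs an abstractable hydrogen, so the carbon adjacent to the alkyl radical must not be quaternary"
    },
    {
      "id": "R-H2O",
      "loss": "H2O",
      "applies_to": [
        "RO2_radical",
        "closed_shell",
        "dimer"
      ],
      "predicate": "has_hydroperoxide",
      "anchor": "water loss from a hydroperoxide group, a standard negative-ion fragmentation channel"
    },
    {
      "id": "R-CO2",
      "loss": "CO2",
      "applies_to": [
        "RO2_radical",
        "closed_shell"
      ],
      "predicate": "has_peroxy_acid",
      "anchor": "charge-migration elimination of CO2, diagnostic of a carboxylic/peroxy-acid moiety"
    },
    {
      "id": "R-OHelim",
      "loss": "OH",
      "applies_to": [
        "RO2_radical"
      ],
      "predicate": "not_tertiary_ro2",
      "anchor": "intramolecular H-abstraction at the peroxy radical followed by OH elimination and ketone formation; impossible for tertiary alkylperoxy radicals"
    },
    {
      "id": "R-HO2",
      "loss": "HO2",
      "applies_to": [
        "RO2_radical"
      ],
      "predicate": "alpha_not_quaternary",
      "anchor": "HO2 elimination; needs a hydrogen on the carbon next to the peroxy radical, so that carbon must not be quaternary"
    },
    {
      "id": "R-CHO3",
      "loss": "CHO3",
      "applies_to": [
        "RO2_radical"
      ],
      "predicate": "radical_near_peroxy",
      "anchor": "CHO3 loss by radical recombination, possible when the radical sits near a peroxy group"
    },
    {
      "id": "R-CH3O2",
      "loss": "CH3O2",
      "applies_to": [
        "RO2_radical"
      ],
      "predicate": "gem_dimethyl",
      "anchor": "methylperoxy loss, indicative of the gem-dimethyl quaternary carbon of the a-pinene skeleton"
    },
    {
      "id": "R-C3H6O",
      "loss": "C3H6O",
      "applies_to": [
        "RO2_radical"
      ],
      "predicate": "gem_dimethyl",
      "anchor": "C3H6O loss, indicative of the gem-dimethyl quaternary carbon of the a-pinene skeleton"
    }
  ]
}
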