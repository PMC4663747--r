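{
  "organism_id": "example_chain",
  "taxonomy": {
    "class": "Bacilli",
    "genus": "Exemplus"
  },
  "metabolites": [
    {
      "id": "bm_c",
      "name": "biomass precursor",
      "compartment": "cytosol"
    },
    {
      "id": "fru_e",
      "name": "fructose (extracellular)",
      "compartment": "extracellular"
    },
    {
      "id": "g6p_c",
      "name": "glucose 6-phosphate",
      "compartment": "cytosol"
    },
    {
      "id": "glc_c",
      "name": "glucose (cytosol)",
      "compartment": "cytosol"
    },
    {
      "id": "glc_e",
      "name": "glucose (extracellular)",
      "compartment": "extracellular"
    }
  ],
  "reactions": [
    {
      "id": "ALT_fru",
      "stoichiometry": {
        "fru_e": -1,
        "g6p_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "is_exchange": false,
      "is_biomass": false
    },
    {
      "id": "biomass",
      "stoichiometry": {
        "bm_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "is_exchange": false,
      "is_biomass": true
    },
    {
      "id": "EX_fru",
      "stoichiometry": {
        "fru_e": -1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "is_exchange": true,
      "is_biomass": false
    },
    {
      "id": "EX_glc",
      "stoichiometry": {
        "glc_e": -1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "is_exchange": true,
      "is_biomass": false
    },
    {
      "id": "HEX",
      "stoichiometry": {
        "g6p_c": 1,
        "glc_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "is_exchange": false,
      "is_biomass": false
    },
    {
      "id": "PRE",
      "stoichiometry": {
        "bm_c": 1,
        "g6p_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "is_exchange": false,
      "is_biomass": false
    },
    {
      "id": "PTS_glc",
      "stoichiometry": {
        "glc_c": 1,
        "glc_e": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "is_exchange": false,
      "is_biomass": false
    }
  ],
  "biomass_reaction_id": "biomass"
}
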