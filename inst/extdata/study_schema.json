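{
  "columns": [
    {
      "name": "publication_id",
      "type": "string",
      "required": true
    },
    {
      "name": "observation_id",
      "type": "string",
      "required": true
    },
    {
      "name": "pub_year",
      "type": "numeric",
      "required": true
    },
    {
      "name": "country",
      "type": "string",
      "required": true
    },
    {
      "name": "taxon_group",
      "type": "string",
      "required": true
    },
    {
      "name": "functional_group",
      "type": "string",
      "required": true
    },
    {
      "name": "crop_type",
      "type": "string",
      "required": true
    },
    {
      "name": "scale",
      "type": "string",
      "required": true
    },
    {
      "name": "mean_org",
      "type": "numeric",
      "required": true
    },
    {
      "name": "sd_org",
      "type": "numeric",
      "required": true
    },
    {
      "name": "n_org",
      "type": "numeric",
      "required": true
    },
    {
      "name": "mean_conv",
      "type": "numeric",
      "required": true
    },
    {
      "name": "sd_conv",
      "type": "numeric",
      "required": true
    },
    {
      "name": "n_conv",
      "type": "numeric",
      "required": true
    },
    {
      "name": "region",
      "type": "string",
      "required": false
    },
    {
      "name": "pct_arable",
      "type": "numeric",
      "required": false
    },
    {
      "name": "n_habitats",
      "type": "numeric",
      "required": false
    },
    {
      "name": "avg_field_size",
      "type": "numeric",
      "required": false
    },
    {
      "name": "richness_surrogate",
      "type": "string",
      "required": false
    }
  ],
  "enums": {
    "taxon_group": ["arthropods", "birds", "microbes", "plants"],
    "functional_group": ["producers", "herbivores", "pollinators", "predators", "decomposers", "other"],
    "crop_type": ["cereals", "grassland", "mixed", "orchard", "vegetables", "miscellaneous"],
    "scale": ["plot", "field", "farm"]
  },
  "synonyms": {
    "grasses": "grassland",
    "grass": "grassland",
    "pasture": "grassland",
    "unspecified": "miscellaneous",
    "misc": "miscellaneous",
    "orchards": "orchard",
    "vegetable": "vegetables",
    "cereal": "cereals",
    "arthropod": "arthropods",
    "bird": "birds",
    "microbe": "microbes",
    "plant": "plants",
    "producer": "producers",
    "herbivore": "herbivores",
    "pollinator": "pollinators",
    "predator": "predators",
    "decomposer": "decomposers",
    "others": "other"
  }
}
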