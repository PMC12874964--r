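[
  {
    "biome": "tundra",
    "order": 1,
    "mat": -16,
    "map": 0
  },
  {
    "biome": "tundra",
    "order": 1,
    "mat": -4,
    "map": 0
  },
  {
    "biome": "tundra",
    "order": 1,
    "mat": -4,
    "map": 30
  },
  {
    "biome": "tundra",
    "order": 1,
    "mat": -16,
    "map": 30
  },
  {
    "biome": "boreal forest",
    "order": 2,
    "mat": -4,
    "map": 10
  },
  {
    "biome": "boreal forest",
    "order": 2,
    "mat": 4,
    "map": 15
  },
  {
    "biome": "boreal forest",
    "order": 2,
    "mat": 4,
    "map": 150
  },
  {
    "biome": "boreal forest",
    "order": 2,
    "mat": -4,
    "map": 130
  },
  {
    "biome": "temperate grassland/desert",
    "order": 3,
    "mat": -4,
    "map": 0
  },
  {
    "biome": "temperate grassland/desert",
    "order": 3,
    "mat": 22,
    "map": 0
  },
  {
    "biome": "temperate grassland/desert",
    "order": 3,
    "mat": 22,
    "map": 15
  },
  {
    "biome": "temperate grassland/desert",
    "order": 3,
    "mat": 4,
    "map": 15
  },
  {
    "biome": "temperate grassland/desert",
    "order": 3,
    "mat": -4,
    "map": 10
  },
  {
    "biome": "woodland/shrubland",
    "order": 4,
    "mat": 4,
    "map": 15
  },
  {
    "biome": "woodland/shrubland",
    "order": 4,
    "mat": 22,
    "map": 15
  },
  {
    "biome": "woodland/shrubland",
    "order": 4,
    "mat": 22,
    "map": 60
  },
  {
    "biome": "woodland/shrubland",
    "order": 4,
    "mat": 4,
    "map": 90
  },
  {
    "biome": "temperate seasonal forest",
    "order": 5,
    "mat": 4,
    "map": 90
  },
  {
    "biome": "temperate seasonal forest",
    "order": 5,
    "mat": 22,
    "map": 60
  },
  {
    "biome": "temperate seasonal forest",
    "order": 5,
    "mat": 22,
    "map": 180
  },
  {
    "biome": "temperate seasonal forest",
    "order": 5,
    "mat": 4,
    "map": 200
  },
  {
    "biome": "temperate rain forest",
    "order": 6,
    "mat": 4,
    "map": 200
  },
  {
    "biome": "temperate rain forest",
    "order": 6,
    "mat": 22,
    "map": 180
  },
  {
    "biome": "temperate rain forest",
    "order": 6,
    "mat": 22,
    "map": 350
  },
  {
    "biome": "temperate rain forest",
    "order": 6,
    "mat": 4,
    "map": 300
  },
  {
    "biome": "subtropical desert",
    "order": 7,
    "mat": 22,
    "map": 0
  },
  {
    "biome": "subtropical desert",
    "order": 7,
    "mat": 30,
    "map": 0
  },
  {
    "biome": "subtropical desert",
    "order": 7,
    "mat": 30,
    "map": 50
  },
  {
    "biome": "subtropical desert",
    "order": 7,
    "mat": 22,
    "map": 50
  },
  {
    "biome": "tropical seasonal forest/savanna",
    "order": 8,
    "mat": 22,
    "map": 50
  },
  {
    "biome": "tropical seasonal forest/savanna",
    "order": 8,
    "mat": 30,
    "map": 50
  },
  {
    "biome": "tropical seasonal forest/savanna",
    "order": 8,
    "mat": 30,
    "map": 250
  },
  {
    "biome": "tropical seasonal forest/savanna",
    "order": 8,
    "mat": 22,
    "map": 230
  },
  {
    "biome": "tropical rain forest",
    "order": 9,
    "mat": 22,
    "map": 230
  },
  {
    "biome": "tropical rain forest",
    "order": 9,
    "mat": 30,
    "map": 250
  },
  {
    "biome": "tropical rain forest",
    "order": 9,
    "mat": 30,
    "map": 450
  },
  {
    "biome": "tropical rain forest",
    "order": 9,
    "mat": 22,
    "map": 450
  }
]
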