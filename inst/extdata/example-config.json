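{
  "simulation": {
    "n_cells": 200,
    "field_shape": [320, 320],
    "composition": {
      "excitatory_neuron": 0.5,
      "astrocyte_mature": 0.2,
      "radial_glia": 0.2,
      "npc": 0.1
    },
    "drift_sd": 2,
    "detachment_rate_per_round": 0.02,
    "noise_sd": 15
  },
  "options": {
    "max_centroid_distance": 10,
    "quality_floor": 0.5
  }
}
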