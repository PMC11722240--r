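{
  "gmm": { "n_restarts": 10, "seed": 7 },
  "tracks": { "rapid_threshold": 0.03, "noise_cap": 0.2 },
  "synth": { "preset": "injured", "n_cells": 50 }
}
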