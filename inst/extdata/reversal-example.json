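{
  "task": "reversal",
  "n_trials": 400,
  "block_length": 100,
  "reward_input": true,
  "reservoir": { "N": 500, "g": 2, "tau": 100 },
  "decision": { "beta": 4, "eta": 0.001 }
}
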