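{
  "planted_sites": [
    {
      "position": 480,
      "target_species": "Cervus_nippon",
      "target_base": "C",
      "background_base": "T"
    },
    {
      "position": 505,
      "target_species": "Cervus_nippon",
      "target_base": "C",
      "background_base": "T"
    }
  ]
}
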