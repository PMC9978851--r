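species_name: "Lymantria dispar dispar"
feeding_instars: [L2, L3, L4, L5, L6]
max_instars: 6
approximate_digestibility: 0.35
notes: >
  Spongy moth. Males complete development at L5, females at L6; the single
  combined L6 column therefore represents roughly half the population. Feeds
  on oak-dominated broadleaf forest from mid-May to early July.
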