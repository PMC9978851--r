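species_name: "Choristoneura pinus"
feeding_instars: [L2, L3, L4, L5, L6, L7]
max_instars: 7
approximate_digestibility: 0.30
notes: >
  Jack pine budworm. Up to seven instars; overwinters in diapause as L2 and
  feeds on jack pine foliage and pollen cones from mid-May to early July.
  AD estimated from the closely related spruce budworm.
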