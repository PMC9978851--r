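species,instar,weight
Choristoneura pinus,L2,0.0099
Choristoneura pinus,L3,0.0098
Choristoneura pinus,L4,0.01
Choristoneura pinus,L5,0.1399
Choristoneura pinus,L6,0.6917
Choristoneura pinus,L7,0.1387
Lymantria dispar dispar,L2,0.0068
Lymantria dispar dispar,L3,0.0068
Lymantria dispar dispar,L4,0.1524
Lymantria dispar dispar,L5,0.4218
Lymantria dispar dispar,L6,0.4122
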