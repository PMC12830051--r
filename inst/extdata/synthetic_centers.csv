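id,observed,expected,donor_rate
p001,58,48.1815,0.214
p002,39,83.4761,0.4797
p003,43,99.9717,0.0878
p004,144,128.7317,0.4439
p005,130,145.1283,-0.3628
p006,114,171.576,0.1227
p007,202,197.8772,-0.8638
p008,256,215.1645,0.4896
p009,281,230.7956,-0.3641
p010,248,259.4688,-1.2942
p011,240,281.6638,-0.7458
p012,356,309.1688,0.9216
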