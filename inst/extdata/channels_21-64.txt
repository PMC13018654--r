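Pz
P1
P2
P3
P4
P5
P6
P7
P8
POz
PO3
PO4
PO5
PO6
PO7
PO8
Oz
O1
O2
CB1
CB2
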