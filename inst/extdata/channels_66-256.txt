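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
PPO1
PPO2
PPO3
PPO4
PPO5
PPO6
POOz
POO1
POO2
POO3
POO4
OI1
OI2
PO9
PO10
P1h
P2h
P3h
P4h
P5h
P6h
PPO1h
PPO2h
PPO3h
PPO4h
PPO5h
PPO6h
PO1h
PO2h
PO3h
PO4h
PO5h
PO6h
POO1h
POO2h
POO3h
POO4h
O1h
O2h
POO9
POO10
I1
I2
CB1h
CB2h
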