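gene	importance_mesa	importance_cedar
ARHGEF18	82.81	72.42
SLC9A1	100.00	42.47
ARHGAP17	83.68	50.20
TACC1	40.01	59.56
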