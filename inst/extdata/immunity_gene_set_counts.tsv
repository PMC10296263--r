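quantity	value
set_size	2112
present_mesa	1802
present_cedar	1715
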