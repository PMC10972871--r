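group	slope
all	1.56
default	1
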