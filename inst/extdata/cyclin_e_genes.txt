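CCNE1
CCNE2
Ccne1
Ccne2
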