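g01
g02
g03
g04
g05
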