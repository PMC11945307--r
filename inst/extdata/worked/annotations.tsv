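g16	W:01
g20	W:01
g06	W:01
g07	W:01
g08	W:01
g09	W:01
g10	W:01
g11	W:01
g12	W:01
g13	W:01
g14	W:01
g15	W:01
g19	W:01
g18	W:01
g17	W:01
g09	W:02
g19	W:02
g10	W:03
g17	W:03
g08	W:04
g06	W:05
g01	W:06
g02	W:06
g03	W:06
g04	W:06
g05	W:06
g11	W:07
g12	W:07
g18	W:07
g13	W:08
g14	W:09
g15	W:10
g07	W:11
g01	W:12
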