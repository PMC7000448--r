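symbol
WFS1
TMEM201
TMEM38A
PLPP7
TMEM214
LPCAT3
KLHL31
BVES
TMEM120A
TMEM170A
NRM
SLC38A10
TMX4
METTL7A
POPDC2
TMEM51
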