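symbol	modes	modifier_only
EMD	XLR	FALSE
LMNA	AD	FALSE
SYNE1	AD	FALSE
SYNE2	AD	FALSE
SUN1	AD	FALSE
SUN2	AD	TRUE
FHL1	XLR	FALSE
TMEM43	AD	FALSE
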