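symbol	modes	modifier_only
CAPN3	AR	FALSE
GBE1	AR	FALSE
VCP	AD	FALSE
TTN	AR	FALSE
COL6A1	AD	FALSE
COL6A2	AD	FALSE
COL6A3	AD	FALSE
CAV3	AD	FALSE
DMD	XLR	FALSE
ANO5	AR	FALSE
DYSF	AR	FALSE
POMT1	AR	FALSE
POMT2	AR	FALSE
FKRP	AR	FALSE
LAMA2	AR	FALSE
SGCA	AR	FALSE
SGCB	AR	FALSE
SGCG	AR	FALSE
SGCD	AR	FALSE
DES	AD	TRUE
MYOT	AD	FALSE
LDB3	AD	FALSE
BAG3	AD	FALSE
PLEC	AR	FALSE
TRIM32	AR	FALSE
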