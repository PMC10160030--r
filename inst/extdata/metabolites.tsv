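name	formula	adduct	verified
citrate/isocitrate	C6H8O7	[M-H]-	TRUE
aconitate	C6H6O6	[M-H]-	TRUE
alpha-ketoglutarate	C5H6O5	[M-H]-	TRUE
succinate	C4H6O4	[M-H]-	TRUE
fumarate	C4H4O4	[M-H]-	TRUE
malate	C4H6O5	[M-H]-	TRUE
oxaloacetate	C4H4O5	[M-H]-	TRUE
quinate	C7H12O6	[M-H]-	TRUE
hexose	C6H12O6	[M-H]-	TRUE
MBOA	C8H7NO3	[M-H]-	TRUE
hexose-hexose	C12H22O11	[M-H]-	FALSE
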