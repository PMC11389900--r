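Fz	AFz
Fz	F1
Fz	F2
Fz	FCz
AFz	F1
F1	F2
F2	FCz
FCz	Cz
CPz	Cz
CPz	CP1
CPz	CP2
CPz	Pz
Cz	CP1
CP1	CP2
CP2	Pz
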