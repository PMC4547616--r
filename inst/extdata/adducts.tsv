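label	atoms_added	atoms_removed	charge
[M.]+			1
[M+H]+	H		1
[M+K]+	K		1
[M+Na]+	Na		1
[M+Li]+	Li		1
[M+NH4]+	NH4		1
[M-H]-		H	-1
[M+Cl]-	Cl		-1
[M+OAc]-	C2H3O2		-1
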