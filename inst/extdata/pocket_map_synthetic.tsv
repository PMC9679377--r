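# SYNTHETIC FIXTURE. Peptide-binding-pocket membership of mhc1 codons
# (alignment codon numbering) for three reference crystal structures.
# Memberships for codons other than 68, 72, 100, 118, and 160 are
# synthetic filler; the chicken CDE pocket is kept pooled, not expanded.
structure	codon	pockets
chicken	68	A,B
human	68	A,B
green_anole	72	B
chicken	72	B,CDE
human	72	B,C
green_anole	100	C,D
chicken	100	A,B,CDE
human	100	A,B,D
green_anole	118	F
chicken	118	F
human	118	F
green_anole	160	A,D
chicken	160	A,CDE
human	160	A,D
green_anole	140	F
human	146	F
chicken	147	F
human	155	E
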