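# SYNTHETIC FIXTURE. Per-codon selection classifications for the mhc1
# exon-2+3 alignment (FEL-style). Classifications at codons other than
# 68, 72, 100, 118, and 160 are synthetic filler.
species	gene	codon	class	source
green_anole	mhc1	68	diversifying	FEL
green_anole	mhc1	72	diversifying	FEL
green_anole	mhc1	30	diversifying	FEL
green_anole	mhc1	155	diversifying	FEL
green_anole	mhc1	100	purifying	FEL
green_anole	mhc1	118	purifying	FEL
green_anole	mhc1	160	purifying	FEL
green_anole	mhc1	140	invariant	FEL
green_anole	mhc1	146	neutral	FEL
green_anole	mhc1	147	invariant	FEL
brown_anole	mhc1	68	diversifying	FEL
brown_anole	mhc1	72	diversifying	FEL
brown_anole	mhc1	100	diversifying	FEL
brown_anole	mhc1	33	diversifying	FEL
brown_anole	mhc1	150	diversifying	FEL
brown_anole	mhc1	158	diversifying	FEL
brown_anole	mhc1	118	purifying	FEL
brown_anole	mhc1	160	neutral	FEL
brown_anole	mhc1	140	invariant	FEL
brown_anole	mhc1	146	neutral	FEL
brown_anole	mhc1	147	neutral	FEL
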