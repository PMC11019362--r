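term	key	dg
# apohm DNA hairpin thermodynamic parameter set, version 1 (37 C, 1 M NaCl).
# Units: kcal/mol. This file is the source of truth for hairpin_delta_g();
# swap values here to use a different parameterisation.
# stack: nearest-neighbor free energies for stacked Watson-Crick pairs,
# keyed by the top-strand dinucleotide read 5'->3' (unified DNA set).
stack	AA	-1.00
stack	AC	-1.44
stack	AG	-1.28
stack	AT	-0.88
stack	CA	-1.45
stack	CC	-1.84
stack	CG	-2.17
stack	CT	-1.28
stack	GA	-1.30
stack	GC	-2.24
stack	GG	-1.84
stack	GT	-1.44
stack	TA	-0.58
stack	TC	-1.30
stack	TG	-1.45
stack	TT	-1.00
# hairpin_loop: loop-initiation penalty by loop size (closing pair not
# counted in the size).
hairpin_loop	3	3.50
hairpin_loop	4	3.50
hairpin_loop	5	3.30
hairpin_loop	6	4.00
hairpin_loop	7	4.20
hairpin_loop	8	4.30
hairpin_loop	9	4.50
hairpin_loop	10	4.60
# special_loop: sequence-specific increments for extra-stable tri/tetra
# loops, keyed by 5'-closing base + loop + 3'-closing base. Applied only
# for loops of size <= 4 (no sequence-specific data beyond that).
special_loop	CGAAG	-1.20
special_loop	CGCAG	-1.00
special_loop	CGAAAG	-1.50
special_loop	GGAAAC	-1.10
special_loop	CTTCGG	-1.20
# mismatch: increment for a single internal non-Watson-Crick pair, keyed
# by the alphabetically sorted base pair.
mismatch	AA	0.70
mismatch	AC	1.00
mismatch	AG	0.40
mismatch	CC	1.20
mismatch	CT	0.90
mismatch	GG	0.30
mismatch	GT	-0.10
mismatch	TT	0.40
# bulge: increment for a bulge loop, keyed by bulge size in nt.
bulge	1	4.00
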