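# Per-residue carbon sites for ion-residue interaction profiling.
# Each site is a carbon two (heavy-atom) bonds away from the residue's main
# charge donor/acceptor atom; backbone default is the alpha-carbon. This
# table is a documented reconstruction against standard amino-acid
# connectivity and is fully overridable by the user.
# columns: resname <TAB> atom <TAB> anchor (the donor/acceptor the site flanks)
LYS	CD	NZ (ammonium nitrogen)
ARG	CD	NH1/NH2/NE (guanidinium)
ASP	CB	OD1/OD2 (carboxylate)
GLU	CG	OE1/OE2 (carboxylate)
HIS	CB	ND1/NE2 (imidazole)
HIE	CB	ND1/NE2 (imidazole)
HID	CB	ND1/NE2 (imidazole)
HIP	CB	ND1/NE2 (imidazole)
SER	CA	OG (hydroxyl)
THR	CA	OG1 (hydroxyl)
TYR	CZ	OH (phenol)
ASN	CB	OD1/ND2 (amide)
GLN	CG	OE1/NE2 (amide)
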