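# Nearest-neighbor intermolecular RNA/RNA duplex parameters (kcal/mol, 37 C).
# Watson-Crick stack values follow the standard Turner-style nearest-neighbor
# set; GU-wobble stacks and loop terms are package defaults chosen to respect
# the usual qualitative ordering (GC-rich stacks most stabilizing, the GG/UU
# tandem wobble destabilizing).  Substitute a custom table via the
# energy-params option; the file must keep all 36 stack entries.
#
# stack notation XY/WZ: top strand 5'-XY-3' over bottom strand 3'-WZ-5';
# the left pair is X:W, the right pair is Y:Z.  The table satisfies the
# rotational symmetry value(XY/WZ) == value(ZW/YX), which makes the duplex
# energy symmetric in its two sequences.
param	init	4.09
param	terminal_au	0.45
param	bulge_open	3.2
param	bulge_ext	0.6
param	internal_open	1.7
param	internal_ext	0.6
param	max_loop	30
stack	AA/UU	-0.93
stack	AU/UA	-1.10
stack	AC/UG	-2.24
stack	AG/UC	-2.08
stack	UA/AU	-1.33
stack	UU/AA	-0.93
stack	UC/AG	-2.35
stack	UG/AC	-2.11
stack	CA/GU	-2.11
stack	CU/GA	-2.08
stack	CC/GG	-3.26
stack	CG/GC	-2.36
stack	GA/CU	-2.35
stack	GU/CA	-2.24
stack	GC/CG	-3.42
stack	GG/CC	-3.26
stack	AG/UU	-0.55
stack	UU/GA	-0.55
stack	AU/UG	-1.36
stack	GU/UA	-1.36
stack	UG/AU	-1.00
stack	UA/GU	-1.00
stack	UU/AG	-1.27
stack	GA/UU	-1.27
stack	CG/GU	-1.41
stack	UG/GC	-1.41
stack	CU/GG	-2.11
stack	GG/UC	-2.11
stack	GG/CU	-1.53
stack	UC/GG	-1.53
stack	GU/CG	-2.51
stack	GC/UG	-2.51
stack	GG/UU	0.47
stack	UU/GG	0.47
stack	GU/UG	-0.57
stack	UG/GU	0.30
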