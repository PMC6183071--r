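# Nearest-neighbor RNA:RNA duplex parameters, Turner 2004 set, 37 degrees C.
# All values in kcal/mol (negative = stabilizing).
#
# Sections (column 1):
#   stack           key = 5'->3' doublet X1X2 on one strand; the energy of the
#                   two stacked Watson-Crick pairs (X1:c(X1))/(X2:c(X2)).
#                   16 entries; reverse-complement symmetric:
#                   stack[X1X2] == stack[revcomp(X1X2)].
#   init            duplex initiation, applied once per duplex.
#   terminal_au     penalty per helix end whose closing pair is A:U or U:A.
#   mismatch_ext_nn terminal mismatch with unknown (N) bases on both strands
#                   outside the helix end; key = closing pair as read outward
#                   (left end: first base + its complement; right end:
#                   complement of last base + last base).
#   int11_nn        1x1 internal loop with unknown (N) bases on both strands;
#                   key = left closing pair "." right closing pair, pairs
#                   encoded as for mismatch_ext_nn. Used for a single interior
#                   abasic/unknown position.
category	key	dg
stack	AA	-0.90
stack	AC	-2.20
stack	AG	-2.10
stack	AU	-1.10
stack	CA	-2.10
stack	CC	-3.30
stack	CG	-2.40
stack	CU	-2.10
stack	GA	-2.40
stack	GC	-3.40
stack	GG	-3.30
stack	GU	-2.20
stack	UA	-1.30
stack	UC	-2.40
stack	UG	-2.10
stack	UU	-0.90
init	.	4.10
terminal_au	.	0.50
mismatch_ext_nn	CG	-0.50
mismatch_ext_nn	GC	-0.80
mismatch_ext_nn	AU	-0.50
mismatch_ext_nn	UA	-0.60
int11_nn	CG.CG	0.90
int11_nn	CG.GC	0.90
int11_nn	CG.AU	1.20
int11_nn	CG.UA	1.20
int11_nn	GC.CG	0.90
int11_nn	GC.GC	0.80
int11_nn	GC.AU	1.20
int11_nn	GC.UA	1.20
int11_nn	AU.CG	1.20
int11_nn	AU.GC	1.20
int11_nn	AU.AU	1.90
int11_nn	AU.UA	1.90
int11_nn	UA.CG	1.20
int11_nn	UA.GC	1.20
int11_nn	UA.AU	1.90
int11_nn	UA.UA	1.90
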