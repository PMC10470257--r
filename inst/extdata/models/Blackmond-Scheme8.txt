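# Kinetic scheme for asymmetric autocatalysis (irreversible form):
# monomer-, homodimer- and heterodimer-catalyzed production of R and S
# from achiral A + Z.  Dimer species RR, SS, SR are spectators (never
# produced), so the scheme cannot break mirror symmetry.
modelname = Blackmond-Scheme8
species = R, S, A, Z, RR, SS, SR
reaction = A + Z -> R
reaction = A + Z -> S
reaction = A + Z + R -> 2 R
reaction = A + Z + S -> 2 S
reaction = A + Z + RR -> R + RR
reaction = A + Z + SS -> S + SS
reaction = A + Z + SR -> R + SR
reaction = A + Z + SR -> S + SR
enantiomeric_pairs = (0,1), (4,5)
dual_pairs = (4,5), (6,7)
option sna.enabled = true
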