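# Limited-enantioselectivity (LES) model: reversible production,
# autocatalysis and LES reactions (imperfect autocatalysis yielding one
# unit of each enantiomer).  With the default dual pairs the autocatalytic
# and LES rate constants are independent (SMSB possible); forcing them
# equal -- dual_pairs = (0,2), (1,3), (4,6), (5,7), (4,8), (4,10), (5,9),
# (5,11) -- removes the symmetry-breaking conditions.
modelname = Blanco-et-al-LES-2013
species = L, D, A
reaction = A <-> L
reaction = A <-> D
reaction = A + L <-> 2 L
reaction = A + D <-> 2 D
reaction = A + L <-> L + D
reaction = A + D <-> D + L
enantiomeric_pairs = (0,1)
option frank-ineq-linear.enabled = true
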