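# Dimerization block of the activation-polymerization-epimerization-
# depolymerization (APED) model: activated monomers Ls/Ds attack L/D.
# The homochiral rate p and the heterochiral rate alpha*p are independent
# constants here (alpha != 1 is required for SMSB); forcing alpha = 1
# corresponds to adding dual pairs (0,2), (1,3).
modelname = APED-dimerization
species = L, D, Ls, Ds, LL, DD, DL, LD
reaction = Ls + L -> LL
reaction = Ds + D -> DD
reaction = Ds + L -> DL
reaction = Ls + D -> LD
enantiomeric_pairs = (0,1), (2,3), (4,5), (6,7)
dual_pairs = (0,1), (2,3)
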