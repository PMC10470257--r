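# Calvin-type model (version 2) in a CSTR, augmented with LES reactions.
# Two enantiomeric pairs (L-A, D-A) and (L-B, D-B); achiral feedstocks
# NR3 and AllylX flow in, everything flows out at a common rate.
modelname = Calvin-2-CSTR-LES
species = L-A, D-A, L-B, D-B, NR3, AllylX
reaction =  -> NR3
reaction =  -> AllylX
reaction = NR3 + AllylX <-> L-A
reaction = NR3 + AllylX <-> D-A
reaction = L-A <-> L-B
reaction = D-A <-> D-B
reaction = L-A + L-B <-> 2 L-B
reaction = D-A + D-B <-> 2 D-B
reaction = L-A + L-B <-> L-B + D-B
reaction = D-A + D-B <-> D-B + L-B
reaction = L-A ->
reaction = D-A ->
reaction = L-B ->
reaction = D-B ->
reaction = NR3 ->
reaction = AllylX ->
enantiomeric_pairs = (0,1), (2,3)
dual_pairs = (2,4), (3,5), (6,8), (7,9), (10,12), (11,13), (14,16), (15,17), (18,19), (18,20), (18,21), (18,22), (18,23)
option frank-ineq-linear.enabled = true
option frank-pseudoquiral.enabled = true
option frank-pseudoquiral.enantiomeric-pairs = (0,1), (2,3)
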