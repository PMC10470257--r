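# All-reversible variant of the asymmetric-autocatalysis scheme, enriched
# with explicit dimerization reactions producing RR, SS and SR.
modelname = Blackmond-Rev-2020
species = R, S, A, Z, RR, SS, SR
reaction = A + Z <-> R
reaction = A + Z <-> S
reaction = A + Z + R <-> 2 R
reaction = A + Z + S <-> 2 S
reaction = R + R <-> RR
reaction = S + S <-> SS
reaction = R + S <-> SR
reaction = A + Z + RR <-> R + RR
reaction = A + Z + SS <-> S + SS
reaction = A + Z + SR <-> R + SR
reaction = A + Z + SR <-> S + SR
enantiomeric_pairs = (0,1), (4,5)
dual_pairs = (8,10), (9,11), (14,16), (15,17), (18,20), (19,21)
option frank-pseudoquiral.enabled = true
option frank-pseudoquiral.enantiomeric-pairs = (0,1), (4,5)
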