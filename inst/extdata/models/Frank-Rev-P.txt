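# Reversible Frank model with explicit product P, closed (no CSTR
# pseudo-reactions).  Stable; its unstable samples are never frank.
modelname = Frank-Rev-P
species = L, D, A, B, P
reaction = A + B <-> L
reaction = A + B <-> D
reaction = A + L <-> 2 L
reaction = A + D <-> 2 D
reaction = L + D <-> P
enantiomeric_pairs = (0,1)
option sna.enabled = true
option frank-ineq-linear.enabled = true
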