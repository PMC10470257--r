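# Fully reversible Frank model with explicit precursors A, B and product
# P, open through CSTR inflow/outflow pseudo-reactions sharing one flow
# constant.
modelname = Frank-Rev-P-AB-CSTR
species = L, D, A, B, P
reaction =  -> A
reaction =  -> B
reaction = A + B <-> L
reaction = A + B <-> D
reaction = A + L <-> 2 L
reaction = A + D <-> 2 D
reaction = L + D <-> P
reaction = A ->
reaction = B ->
reaction = L ->
reaction = D ->
reaction = P ->
enantiomeric_pairs = (0,1)
dual_pairs = (12,13), (12,14), (12,15), (12,16)
option sna.enabled = true
option frank-ineq-linear.enabled = true
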