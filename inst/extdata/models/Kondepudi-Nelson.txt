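# Kondepudi-Nelson model: direct production, decay, first-order
# autocatalysis, second-order decomposition and mutual inhibition of an
# enantiomeric pair.  Shipped pre-expanded (all irreversible) so reaction
# indices 0..8 match the standard parsed order.
modelname = Kondepudi-Nelson
species = L, D
reaction =  -> L
reaction =  -> D
reaction = L ->
reaction = D ->
reaction = L -> 2 L
reaction = D -> 2 D
reaction = 2 L -> L
reaction = 2 D -> D
reaction = L + D ->
enantiomeric_pairs = (0,1)
option trace-determinant.enabled = true
option trace-determinant.2by2-jacobian = true
option trace-determinant.num-samples = 10
option sna.enabled = true
option sna.dual-pairs-in-ec = false
option sna.instability-heuristic = mineurs
option sna.sum-mineurs = true
option sna.max-mineur-search-stop = 5
option sna.simplification-tries = 10000
option sna.num-samples = 10
option six-categories.enabled = true
option six-categories.num-samples = 10
option frank-ineq-nonlinear.enabled = true
option frank-ineq-linear.enabled = true
option frank-ineq-linear.dual-pairs-in-ec = true
option frank-ineq-linear.num-samples = 10
option frank-ineq-linear.samples-for-proportion = 10000
option frank-pseudoquiral.enabled = true
option frank-pseudoquiral.enantiomeric-pairs = (0,1)
option frank-pseudoquiral.instability-heuristic = mineurs
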