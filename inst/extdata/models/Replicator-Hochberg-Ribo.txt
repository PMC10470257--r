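# Two-replicator model with cross-catalysis: two enantiomeric pairs
# (R1D, R1L) and (R2D, R2L) feeding on an achiral resource A, with common
# decay/outflow rates.  Species 1RD etc. are written R1D etc. because
# tokens may not start with a digit.
modelname = Replicator-Hochberg-Ribo
species = R1D, R1L, R2D, R2L, A
reaction = A + R1D + R2D <-> 2 R1D + R2D
reaction = A + R1L + R2L <-> 2 R1L + R2L
reaction = A + R2D + R1D <-> 2 R2D + R1D
reaction = A + R2L + R1L <-> 2 R2L + R1L
reaction = R1D ->
reaction = R1L ->
reaction = R2D ->
reaction = R2L ->
reaction =  -> A
reaction = A ->
enantiomeric_pairs = (0,1), (2,3)
# The cross-catalytic replication steps share one forward and one backward
# rate constant across both replicator pairs (groups {0,2,4,6} and
# {1,3,5,7}); decays and the A outflow share the common flow constant.
dual_pairs = (0,2), (1,3), (4,6), (5,7), (0,4), (1,5), (8,9), (8,10), (8,11), (8,13)
option frank-pseudoquiral.enabled = true
option frank-pseudoquiral.enantiomeric-pairs = (0,1), (2,3)
option frank-pseudoquiral.instability-heuristic = trace-determinant
option frank-pseudoquiral.num-samples = 10
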