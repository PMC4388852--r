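# Five-node worked-example logical network.
# Reconstructed from the published worked example by constraint
# satisfaction: reproduces its four stable motifs, the stable motifs of
# every once-reduced network, the four attractors, all four stable motif
# control sets and the blocking set of the third attractor.
A* = A and (B or not E)
B* = A
C* = B or not E
D* = (C and not E) or (D and not B) or (E and not B)
E* = E or (not D and not B)
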