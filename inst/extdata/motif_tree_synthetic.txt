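# Synthetic Phylotree-style haplogroup motif tree (simplified motifs).
# One node per line: two-space indentation gives the depth, then the
# haplogroup name and its defining variants relative to the parent node.
# The root is the rCRS-anchored node (H2a2a1). Motifs are a synthetic
# stand-in: structural facts are preserved (V22 carries the coding-region
# diagnostic transition at np 7765; the V path carries the np 150 hotspot
# transition; U5b1f/J1c5c1/V22 stems carry 3/3/2 defining variants) but the
# remaining positions are illustrative, not the published motifs.
H2a2a1
  HV0 16298
    V 4580 150
      V22 7765 15671
  U 11467 12308
    U5 16270 16192
      U5b 150 14182
        U5b1 5656
          U5b1f 4218 9477 16320
  J 16069 16126
    J1 14798
      J1c 482
        J1c5 9632
          J1c5c 5460
            J1c5c1 185 222 16145
  K 16224 16311
  T 16294
  I 16129 16223
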