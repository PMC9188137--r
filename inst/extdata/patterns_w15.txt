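# Four spaced-seed patterns of weight 15, span 25 (1 = match, 0 = don't care).
# Chosen with minimal pairwise match-position overlap so that joint matching
# has negligible seed-level redundancy between patterns, as holds for
# optimizer-produced sets; any external pattern optimizer's output can be
# substituted via the same file format.
w15a	1101000010111111011000111
w15b	1110001111101000011110101
w15c	1110111100010010101011011
w15d	1001111111110101000101001
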