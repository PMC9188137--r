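# Four spaced-seed patterns of weight 14.
w14a	111100110001111010111
w14b	11010000101111010111011
w14c	10001111001011011101011
w14d	10001110110101111010101
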