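# Four spaced-seed patterns of weight 8 (second pass of the two-step filter).
w8a	10011011101001
w8b	1100011100111
w8c	1010101100011001
w8d	1010011100001101
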