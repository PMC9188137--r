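# Single high-weight pattern (weight 19) for the first pass of the
# two-step geometric hashing filter.
w19	111011000101111101111011011
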