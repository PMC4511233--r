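pair_type	count
trophic	869
mutualism	5
commensalism	208
amensalism	492
competition	324
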