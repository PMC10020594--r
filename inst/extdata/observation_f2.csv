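population,n_high,n_low
f2_epizingiberene,12,380
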