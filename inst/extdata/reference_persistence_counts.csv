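population,n_total,n_persistent,n_non_persistent
naive,64,33,31
total,77,42,35
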