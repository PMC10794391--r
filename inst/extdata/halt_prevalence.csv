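label,n_headphones,n_total
A,80,211
B,211,1194
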