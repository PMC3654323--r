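k,canonical_correlation
1,0.507
2,0.327
3,0.267
4,0.152
5,0.123
6,0.028
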