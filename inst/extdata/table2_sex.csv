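level,n,rate_pct
female,3422,21.2
male,3131,19.7
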