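id,log2fc
RibA,1.0
RibD,0.7
GlyK,0.2
PurF,-0.1
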