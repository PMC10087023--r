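monomer	class
1	coil
2	ahelix
3	coil
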