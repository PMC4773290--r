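id	pos	ref	alt
rs6690733	16	A	C
rs10889352	16	T	C
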