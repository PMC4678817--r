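position	A	C	G	T
19	0.996	0.001	0.002	0.001
20	0.002	0.002	0.995	0.001
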