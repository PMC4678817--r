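position	A	C	G	T
4	0.002	0.001	0.995	0.002
5	0.002	0.002	0.003	0.993
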