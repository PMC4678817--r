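base	freq
A	0.27
C	0.23
G	0.23
T	0.27
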