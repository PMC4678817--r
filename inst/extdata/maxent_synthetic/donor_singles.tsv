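position	A	C	G	T
1	0.3300000000000000	0.3700000000000001	0.180000000000000	0.1200000000000000
2	0.6000000000000001	0.1300000000000000	0.140000000000000	0.1300000000000000
3	0.1399103907726593	0.0466367969242197	0.689088020505202	0.1243647917979194
4	0.6308051625014918	0.0279939763244636	0.313206884849581	0.0279939763244636
5	0.7270014317955859	0.0746506035319030	0.114366035699120	0.0839819289733909
6	0.0508460258376106	0.0610152310051327	0.840763115776182	0.0473756273810749
7	0.1351131823637217	0.1531282733455513	0.171143364327381	0.5406151799633461
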