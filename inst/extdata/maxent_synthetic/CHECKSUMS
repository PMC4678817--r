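file	md5
background.tsv	0838f4a93c8d85532e40347ffd7c0ad6
donor_consensus.tsv	54968ab05f0029b418ffcabf515af0eb
donor_singles.tsv	57f9ee4db6f3cb74002347df01de9229
donor_pairs.tsv	6303557a72647e56507c9395f68598b8
acceptor_consensus.tsv	1be143bb1b383104a0054597b7f650f9
acceptor_singles.tsv	1f16a6e2a4900322ee42ea613c3e112a
acceptor_pairs.tsv	a47d55ac0ba39ed74568f4a53c9f9cd5
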