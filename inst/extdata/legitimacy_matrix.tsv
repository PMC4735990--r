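# Contact legitimacy between atom hydropathy classes: 1 = legitimate,
# 0 = illegitimate. Hydrophilic classes pair legitimately only where
# donor/acceptor pairing holds; hydrophilic-hydrophobic contacts are
# always illegitimate (the load-bearing rule, enforced by a validator).
class	donor	acceptor	donor_acceptor	hydrophobic	neutral
donor	0	1	1	0	1
acceptor	1	0	1	0	1
donor_acceptor	1	1	1	0	1
hydrophobic	0	0	0	1	1
neutral	1	1	1	1	1
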