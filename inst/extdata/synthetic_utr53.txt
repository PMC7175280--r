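# SYNTHETIC 53-nt vector 5' UTR fixture (contains AGGAGA RBS)
GGTACCGAGCTCGAATCTTTCACACAGAATTCATTAAAGAGGAGAAATTAACC
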