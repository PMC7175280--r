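>synthetic_window_fixture (structure is a SYNTHETIC stand-in, not an RNAfold run)
GGTACCGAGCTCGAATCTTTCACACAGAATTCATTAAAGAGGAGAAATTAACCATGGCAAA
..(((((.....)))))............................................ (-4.20)
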