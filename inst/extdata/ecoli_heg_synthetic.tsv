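# SYNTHETIC highly-expressed-gene reference counts (fixture)
AAA	2755
AAC	1355
AAG	430
AAT	1020
ACA	251
ACC	1509
ACG	721
ACT	336
AGA	30
AGC	844
AGG	19
AGT	336
ATA	111
ATC	1725
ATG	2009
ATT	2309
CAA	762
CAC	367
CAG	2187
CAT	606
CCA	307
CCC	153
CCG	1509
CCT	225
CGA	74
CGC	1406
CGG	153
CGT	1305
CTA	74
CTC	398
CTG	5228
CTT	464
GAA	3586
GAC	1112
GAG	1020
GAT	2560
GCA	1255
GCC	1780
GCG	2755
GCT	803
GGA	279
GGC	2248
GGG	464
GGT	1670
GTA	464
GTC	762
GTG	1836
GTT	1065
TAC	533
TAT	887
TCA	251
TCC	307
TCG	336
TCT	307
TGC	200
TGG	762
TGT	131
TTA	682
TTC	887
TTG	931
TTT	1406
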