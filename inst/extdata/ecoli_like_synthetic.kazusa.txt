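# E. coli-like host: SYNTHETIC fixture codon usage table
# per-1000 frequencies (counts in parentheses); values are
# plausible stand-ins for testing, not measurements
UUU 22.0(  4400)  UUC 16.5(  3300)  UUA 14.0(  2800)  UUG 17.0(  3400)
CUU 11.0(  2200)  CUC 10.0(  2000)  CUA  3.5(   700)  CUG 50.0( 10000)
AUU 30.0(  6000)  AUC 25.0(  5000)  AUA  4.5(   900)  AUG 27.5(  5500)
GUU 18.5(  3700)  GUC 15.0(  3000)  GUA 11.0(  2200)  GUG 26.0(  5200)
UCU  8.5(  1700)  UCC  8.5(  1700)  UCA  7.5(  1500)  UCG  9.0(  1800)
AGU  9.0(  1800)  AGC 16.0(  3200)  CCU  7.0(  1400)  CCC  5.5(  1100)
CCA  8.5(  1700)  CCG 23.0(  4600)  ACU  9.0(  1800)  ACC 23.0(  4600)
ACA  7.5(  1500)  ACG 14.5(  2900)  GCU 15.5(  3100)  GCC 25.5(  5100)
GCA 20.5(  4100)  GCG 33.5(  6700)  UAU 16.5(  3300)  UAC 12.0(  2400)
CAU 13.0(  2600)  CAC  9.5(  1900)  CAA 15.0(  3000)  CAG 29.0(  5800)
AAU 18.0(  3600)  AAC 21.5(  4300)  AAA 33.5(  6700)  AAG 10.5(  2100)
GAU 32.0(  6400)  GAC 19.0(  3800)  GAA 39.5(  7900)  GAG 18.0(  3600)
UGU  5.0(  1000)  UGC  6.5(  1300)  UGG 15.0(  3000)  CGU 21.0(  4200)
CGC 22.0(  4400)  CGA  3.5(   700)  CGG  5.5(  1100)  AGA  2.0(   400)
AGG  1.5(   300)  GGU 24.5(  4900)  GGC 29.5(  5900)  GGA  8.0(  1600)
GGG 11.0(  2200)  UAA  2.0(   400)  UAG  0.2(    40)  UGA  1.0(   200)
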