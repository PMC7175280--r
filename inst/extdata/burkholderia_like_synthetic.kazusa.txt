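# Burkholderia-like native: SYNTHETIC fixture codon usage table
# per-1000 frequencies (counts in parentheses); values are
# plausible stand-ins for testing, not measurements
UUU  7.0(  1400)  UUC 25.0(  5000)  UUA  1.5(   300)  UUG  6.0(  1200)
CUU  5.5(  1100)  CUC 18.0(  3600)  CUA  1.5(   300)  CUG 60.0( 12000)
AUU  8.0(  1600)  AUC 32.0(  6400)  AUA  1.5(   300)  AUG 23.0(  4600)
GUU  5.5(  1100)  GUC 25.0(  5000)  GUA  3.0(   600)  GUG 28.0(  5600)
UCU  3.0(   600)  UCC  9.0(  1800)  UCA  2.5(   500)  UCG 16.0(  3200)
AGU  3.5(   700)  AGC 18.0(  3600)  CCU  3.5(   700)  CCC  7.5(  1500)
CCA  3.0(   600)  CCG 25.0(  5000)  ACU  3.0(   600)  ACC 18.0(  3600)
ACA  2.5(   500)  ACG 18.5(  3700)  GCU  7.0(  1400)  GCC 35.0(  7000)
GCA  8.0(  1600)  GCG 38.0(  7600)  UAU  7.5(  1500)  UAC 15.5(  3100)
CAU  7.5(  1500)  CAC 12.5(  2500)  CAA  8.0(  1600)  CAG 23.0(  4600)
AAU  7.5(  1500)  AAC 20.0(  4000)  AAA  9.0(  1800)  AAG 24.0(  4800)
GAU 15.0(  3000)  GAC 32.0(  6400)  GAA 22.0(  4400)  GAG 28.0(  5600)
UGU  2.0(   400)  UGC  7.0(  1400)  UGG 14.0(  2800)  CGU  6.0(  1200)
CGC 28.0(  5600)  CGA  3.5(   700)  CGG 10.5(  2100)  AGA  1.0(   200)
AGG  1.5(   300)  GGU  8.0(  1600)  GGC 38.0(  7600)  GGA  4.5(   900)
GGG  7.5(  1500)  UAA  0.5(   100)  UAG  0.8(   160)  UGA  2.2(   440)
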