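# Mouse-like native: SYNTHETIC fixture codon usage table
# per-1000 frequencies (counts in parentheses); values are
# plausible stand-ins for testing, not measurements
UUU 17.0(  3400)  UUC 21.5(  4300)  UUA  6.8(  1360)  UUG 13.6(  2720)
CUU 13.2(  2640)  CUC 12.0(  2400)  CUA  8.0(  1600)  CUG 40.0(  8000)
AUU 15.5(  3100)  AUC 22.5(  4500)  AUA  7.5(  1500)  AUG 22.5(  4500)
GUU 10.5(  2100)  GUC 15.0(  3000)  GUA  7.5(  1500)  GUG 28.5(  5700)
UCU 16.0(  3200)  UCC 18.0(  3600)  UCA 11.5(  2300)  UCG  4.5(   900)
AGU 12.5(  2500)  AGC 19.5(  3900)  CCU 18.5(  3700)  CCC 18.0(  3600)
CCA 17.0(  3400)  CCG  6.0(  1200)  ACU 13.5(  2700)  ACC 19.0(  3800)
ACA 16.0(  3200)  ACG  5.5(  1100)  GCU 20.0(  4000)  GCC 26.0(  5200)
GCA 15.5(  3100)  GCG  6.5(  1300)  UAU 12.0(  2400)  UAC 16.0(  3200)
CAU 10.5(  2100)  CAC 15.0(  3000)  CAA 12.0(  2400)  CAG 34.5(  6900)
AAU 15.5(  3100)  AAC 20.0(  4000)  AAA 21.5(  4300)  AAG 34.0(  6800)
GAU 21.0(  4200)  GAC 26.0(  5200)  GAA 27.0(  5400)  GAG 39.5(  7900)
UGU 11.5(  2300)  UGC 12.5(  2500)  UGG 12.5(  2500)  CGU  4.5(   900)
CGC  9.0(  1800)  CGA  6.5(  1300)  CGG 10.0(  2000)  AGA 12.0(  2400)
AGG 12.0(  2400)  GGU 11.5(  2300)  GGC 21.5(  4300)  GGA 16.5(  3300)
GGG 15.0(  3000)  UAA  1.0(   200)  UAG  0.8(   160)  UGA  1.6(   320)
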