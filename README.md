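# codonharmony

A codon-harmonization workbench for recombinant gene design.  When a
eukaryotic (or chimeric multi-species) gene is expressed in a bacterial
host, replacing every codon with the host's most abundant synonym — full
codon optimization — maximizes translation speed but can outrun
co-translational folding.  Codon *harmonization* instead chooses host
codons whose **relative codon usage** (RCU, the codon's frequency as a
percentage of its most-used synonym; the family maximum scores 100%)
mirrors the native gene's codon-by-codon usage landscape, preserving the
regions of slow translation that the native sequence encodes.  The
package is aimed at protein expression labs designing constructs for
difficult targets (e.g. isotopically labelled membrane proteins) and at
anyone who wants to diagnose a coding sequence's codon-usage landscape.

## What it computes

**Design engines** (all preserve the encoded protein exactly; chimeric
genes are handled region by region, each segment scored against its own
native-species usage table):

- **FO** — full optimization: every codon becomes the host family
  maximum (RCU 100).
- **DO** — deoptimization to match the native landscape: pick the host
  synonym closest in RCU to the native codon's, excluding candidates
  more than 5 percentage points *below* it.
- **NT** — no tolerance: pick the host synonym with the closest RCU not
  exceeding the native codon's.
- **FT** — full tolerance: a seeded stochastic rule; every host synonym
  gets a likelihood for selection (LSR) decreasing with
  |RCU_host − RCU_native|, and a cumulative random walk over the
  LSR-ranked candidates makes the draw, one uniform number per codon.

**Diagnostics:**

- **%MinMax** profile: over a sliding window of 18 codons, with
  X_actual/X_max/X_min/X_avg the window means of the actual, maximal,
  minimal and average synonymous usage frequencies,

      %MinMax = +100 (X_actual − X_avg) / (X_max − X_avg)   if X_actual > X_avg
                −100 (X_avg − X_actual) / (X_avg − X_min)   if X_actual < X_avg

  so +100 marks windows of only the most abundant codons and −100
  windows of only the rarest; a seeded random-reverse-translation null
  model is provided for comparison.
- **CAI** (geometric mean of w = RCU/100 under a reference table),
  **Nc** (effective number of codons, 20–61, plug-in Wright estimator
  `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`), **ARCU** (mean per-codon RCU),
  **GC content**, and **rare-codon annotation** (native RCU < 40%).
- **5′-mRNA RBS occlusion**: assembles the translation-initiation window
  (vector context −N…−1 plus coding +1…+8), locates the AGGAGA
  ribosome-binding site, attaches either an imported RNAfold dot-bracket
  structure or a built-in base-pair-maximization fold, and reports
  whether any RBS nucleotide is paired.

Everything is exercisable offline: three clearly synthetic fixture usage
tables (E. coli-like, mouse-like, Burkholderia-like) and a synthetic
chimeric-gene generator with a per-position truth ledger are bundled.

## Worked example

```r
library(codonharmony)

mouse <- load_usage_table(fixture_table_path("mouse"), species_label = "mouse")
ecoli <- load_usage_table(fixture_table_path("ecoli"), species_label = "ecoli")

# a 120-codon synthetic gene with ~25% rare codons under the mouse table
gene <- generate_synthetic_gene(120, 0.25, mouse, seed = 42)

res <- harmonize_do(gene$sequence, native = mouse, host = ecoli)
res
#> DO harmonization: 121 codons, 75 substituted, host ecoli

head(res$ledger[, c("position", "amino_acid", "native_codon", "native_rcu",
                    "chosen_codon", "host_rcu")], 4)
#>   position amino_acid native_codon native_rcu chosen_codon host_rcu
#> 1        1          M          ATG  100.00000          ATG      100
#> 2        2          K          AAA   63.23529          AAA      100
#> 3        3          F          TTC  100.00000          TTT      100
#> 4        4          P          CCC   97.29730          CCG      100

metric_report(res$sequence, host = ecoli, native = mouse)
#> CAI 0.733 | Nc 29.6 | ARCU 71.2% | GC 47.1% | 29 rare codon(s) of 121

# the fully optimized construct for comparison
fo <- harmonize_fo(gene$sequence, ecoli)
metric_report(fo$sequence, host = ecoli, native = mouse)
#> CAI 1.000 | Nc 20.0 | ARCU 81.9% | GC 55.1% | 15 rare codon(s) of 121
```

The DO ledger reads: each native codon's RCU (e.g. Lys AAA at 63% in
the mouse-like table) is matched by the closest feasible host codon
(here AAA itself, since the other host Lys codon sits more than 5
points below).  The metric report shows the harmonized construct is
deliberately less "optimal" than FO — CAI 0.73 vs 1.00, Nc 29.6 vs the
maximally biased 20 — because it reproduces the native gene's mix of
common and rare codons (29 rare positions) rather than erasing it.

RBS occlusion of the initiation region:

```r
utr <- readLines(system.file("extdata", "synthetic_utr53.txt",
                             package = "codonharmony"))[2]
w <- fold_window(build_window(utr, res$sequence))
rbs_occlusion(w)
#> $verdict
#> [1] "occluded"
#> $rbs_paired_fraction
#> [1] 0.8333333
```

A command-line shell over the same functions lives at
`system.file("scripts", "codonharmony-cli.R", package = "codonharmony")`
with `harmonize`, `profile` and `fold-window` subcommands.

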