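---
title: "Codon harmonization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon harmonization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonharmony)
```

## The problem

Heterologous expression replaces a gene's codons with synonyms readable
by the host's tRNA pool.  Full optimization — always choosing the host's
most abundant synonym — maximizes elongation speed, but translation
speed and co-translational folding are coupled: the native gene's rare
codons concentrate where the nascent chain needs time to fold, and
erasing them can trade yield of *folded* protein for raw speed.  Codon
harmonization instead reproduces the native usage landscape in the
host's codon vocabulary.  This package implements four design engines
and the diagnostics used to audit them, for single-species genes and for
chimeric genes whose segments descend from different organisms.

## Relative codon usage

All engines operate on **relative codon usage** (RCU, also called
relative adaptiveness): a codon's usage frequency as a percentage of the
most-used codon in its synonymous family, so every family maximum scores
exactly 100.  RCU is scale-free — tables given as raw counts, per-1000
frequencies or proportions produce identical RCU — and `codon_usage_table()`
enforces this by construction (the family maximum is computed as
`100 * (f / max(f))`, which is exactly 100 in floating point).  Ties for
the family maximum all score 100: relative adaptiveness is a ratio and
ties are legitimate.  Stop codons are excluded from normalization by
default; when present they form their own three-codon family so the
terminal stop of a construct can still be described.  Zero-frequency
codons are representable (RCU 0), but the design engines never emit one
unless it is the only synonym available.

Tables load from the common public whitespace grammar
(`CODON freq (count)`, RNA or DNA alphabet; `dialect = "kazusa"`) or
from a bare two-column TSV (`codon<TAB>count`).  The three bundled
tables are *synthetic fixtures* — plausible, clearly labelled stand-ins
that make every workflow runnable offline — not authoritative
measurements; analyses of real constructs should load the genuine
species tables.

## The four engines

Let `n` be the native codon's RCU in its segment's table and consider
the host synonyms of the same amino acid with RCUs `h_1 … h_k`.

* **FO**: choose the host codon with `h = 100` (lexicographically
  smallest on ties).  The output's average RCU is 100 by definition.
* **DO** (tolerance default 5 points): feasible candidates satisfy
  `h >= n - 5`; among them the codon minimizing `|h - n|` is chosen.
  The host family maximum is always feasible, so the rule never fails.
  The tolerance is read as **percentage points** of relative usage, not
  a relative 5%: with the bundled tables a native codon at RCU 33 may
  take a host codon at 28 but not at 27.9, which is the only reading
  consistent with the leucine worked examples the rule is defined by
  (native CTT at 33% takes host TTG at 34%; native CTC at 30% takes TTA
  at 28% while CTT at 22% is excluded).  When both a higher and a lower
  candidate are equidistant the higher host RCU wins, then the
  lexicographically smallest codon — deterministic, and biased toward
  expressibility.
* **NT**: feasible candidates satisfy `h <= n`; the maximal feasible
  `h` (closest from below) is chosen.  When every host synonym exceeds
  `n` there is no defined choice, so the engine falls back to the
  minimal-RCU synonym — the closest achievable from below — and the
  ledger records `nt-fallback`.
* **FT**: every synonym is a candidate.  Each receives a likelihood for
  selection (LSR); candidates are ranked by decreasing LSR, one uniform
  draw `u` is made per codon position in sequence order, and the walk
  selects the first candidate whose cumulative LSR exceeds `u`.  The
  walk terminates because the LSRs sum to 1.  The **functional form**
  of the LSR is the package's own choice:
  `s_i = max(100 - |h_i - n|, 1e-6)`, normalized.  The defining
  requirements — selection likelihood decreases with the absolute
  RCU difference, and the cumulative-draw mechanics — are fixed; the
  linear score is the simplest form satisfying them and is isolated in
  `compute_lsr()` so it can be replaced.  The `1e-6` floor keeps every
  candidate selectable (and the distribution proper) even at the
  maximal difference of 100 points.

All engines: a terminal stop codon is preserved verbatim; an internal
stop is a frame error naming the position; the substitution ledger
records, per codon, the native codon and RCU, the feasible set, the
chosen codon and host RCU, and the rule applied, so every decision is
auditable.  Coordinates are 1-based codon indices throughout.

FT randomness goes through a single seeded generator, one draw per
position in order (positions whose amino acid has one codon still sit in
the draw sequence, so ledgers line up across rules); runs with the same
seed are bit-identical, and the caller's RNG state is left untouched.

### Region-wise application

A `region_map()` assigns contiguous, non-overlapping codon intervals to
named native tables, covering the full gene (the terminal stop may be
left uncovered; it is never scored).  Each codon's native RCU is looked
up in its own segment's table — the mechanism by which a chimera's
eukaryotic and prokaryotic parts are harmonized against their own
species.

### GC biasing and motif surveillance

`apply_gc_bias()` is a greedy left-to-right pass that may swap a chosen
codon for a synonym whose host RCU lies within `slack_points` of it *and*
that remains feasible under the active rule, whenever the swap moves
whole-sequence GC content toward the target; `|GC - target|` is
monotonically non-increasing.  `slack_points = 0` disables the pass
outright: equal-RCU synonyms technically satisfy a zero slack, but a
"zero slack" request is read as "do not trade usage accuracy for GC at
all".  The mechanism behind published GC-content presets is not
specified anywhere we could follow, so this greedy pass is the package's
own, deliberately conservative design.  `scan_forbidden_motifs()`
reports exact matches of cloning-relevant motifs (defaults: NcoI CCATGG,
BamHI GGATCC) at every overlapping offset; repair is intentionally
manual, since automatic synonymous repair can silently undo the
harmonization pattern.

## Diagnostics

**%MinMax** slides a window (default 18 codons — the scale at which
codon-optimality clusters are conventionally judged) and contrasts the
mean usage frequency of the actual codons with the means of the
family-maximal, family-minimal and family-average frequencies at those
positions.  The score is +100 when every window codon is its family
maximum, −100 when every codon is its family minimum, 0 at the average;
raw frequencies can be on any scale since the ratios cancel it.  Windows
are reported at their first codon and only full windows are emitted —
the edge convention is not standardized, and partial windows would mix
window sizes within one trace.  Windows where X_max = X_avg (all
single-codon families) are defined as 0.

The **null model** reverse-translates the protein `n_replicates` times
(default 100 — enough to make the Monte-Carlo error of a window mean
small relative to the ±100 scale, while keeping the default run
interactive), sampling codons by their per-amino-acid frequency, and
averages the per-window traces.  A seed is required rather than
defaulted, so no two analyses silently share randomness.

**CAI** is the geometric mean of `w = RCU/100` under a reference table,
excluding Met, Trp and stops (their `w` is identically 1 and would only
dilute the signal).  The proper reference is a highly-expressed-gene
set; since none is bundled beyond a synthetic fixture, the host table is
the default stand-in — CAI values are then interpretable relative to the
host genome rather than its translational elite, which is the honest
choice when no curated set is supplied.  A zero-weight codon is an error
by default (`zero_weight = "pseudo"` substitutes `0.5/family size`).

**Nc** uses the plug-in estimator: family homozygosity
`F = sum(p_i^2)` over observed synonymous proportions, averaged within
each degeneracy class, and `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`.  The
plug-in form is the default because its analytic bounds are exact: a
sequence using one codon per amino acid gives every `F = 1` and
`Nc = 20`; perfectly uniform usage gives `F_k = 1/k` and `Nc = 61`.
Wright's bias-corrected variant (`method = "wright"`) is available but
requires at least two observations per family.  A degeneracy class with
no observed family contributes `F = 1` (maximal bias) — with nothing to
average, assuming no diversity is the conservative completion.  Results
are clamped to [20, 61] by default.

**ARCU** is the arithmetic mean of per-codon RCU (stop excluded), and
accepts a region map, so a chimera can be scored against its native
species per segment or against the host throughout — both readings of
"average relative usage" are meaningful and both are supported.

**Rare codons** are positions with native RCU strictly below 40: the
threshold is a convention for "rare", the comparison is strict so that
a codon at exactly 40 is not rare.

## The 5′-mRNA window

Translation initiation is sensitive to secondary structure around the
ribosome-binding site.  `build_window()` assembles vector context
(−N…−1) plus the first 8 coding nucleotides — the ribosomal footprint is
taken to extend through +8, and the upstream extent is configurable
because it depends on the vector (53 nt in the bundled fixture).  The
RBS (AGGAGA) is located by exact search in the upstream part; with
several matches the rightmost — closest to the start codon — is the
functional candidate, and all matches are logged.

Thermodynamic minimum-free-energy folding is deliberately **not**
implemented: energies belong to external folders (RNAfold), whose
dot-bracket output `import_structure()` ingests, storing any trailing
energy as an annotation only.  The built-in `fold_bpmax()` is a
Nussinov-style base-pair-maximization dynamic program (Watson–Crick
plus G:U wobble, toggleable; minimum hairpin loop 3 nt; deterministic
traceback pairing each closing base with its leftmost optimal partner).
It is a qualitative pairing-potential scan, not an energy model — useful
for flagging windows worth a real fold, and exactly verifiable against
exhaustive enumeration, which the test suite does.

The occlusion verdict is binary: the RBS is occluded when **any** of its
six nucleotides is paired.  Published free/occluded dichotomies give no
fraction cutoff; any-paired is the most sensitive monotone rule (adding
pairs can never flip occluded to free), and the paired fraction is
reported alongside so users can apply their own threshold.

## The synthetic-gene generator

`generate_synthetic_gene()` emulates the object the engines were built
for: a chimeric gene with a mixed optimal/rare codon composition.  After
a forced ATG, each position draws from its segment table's rare pool
(RCU < 40) with probability `fraction_rare`, otherwise from the
non-rare pool, sampling within the pool by usage frequency; a terminal
stop is appended and a per-position truth ledger (codon, native RCU,
rare flag, table id) is returned.  The generator refuses a nonzero
`fraction_rare` against a table with no rare codons rather than silently
under-delivering.

What it does *not* emulate: real genes' amino-acid composition,
autocorrelation of rare codons along the sequence (rare clusters at
domain boundaries), codon-pair effects, and any mRNA-level selection.
Passing tests therefore demonstrate the algorithms' contracts —
translation preservation, floor/ceiling guarantees, distributional
correctness — on landscape-like inputs, not biological performance on
real constructs.

## Numerical and testing choices

* RCU family maxima are exact (division before scaling); per-family
  frequencies sum to 1 within 1e-9.
* The FT walk uses `findInterval` on the cumulative LSR with a final
  clamp, so a draw of `u` within rounding of 1 still selects the last
  candidate.
* Degenerate inputs fail loudly: empty sequences, internal stops (with
  position), out-of-frame lengths, non-ACGT characters (with offset),
  all-zero families (with the amino acid named), structures of the
  wrong length or with unbalanced brackets.
* Test problem sizes: translation preservation runs all four engines on
  1,000 synthetic 40-codon chimeric genes; the FT distribution is
  checked over 10,000 draws against 3 binomial standard errors; the
  folder is verified against exhaustive enumeration on *all* sequences
  up to 8 nt and 500 random 9–12-mers; %MinMax is checked against an
  independently coded direct evaluation on a 19-codon gene.  These sizes
  make the statistical checks sharp while keeping the default suite
  quick on a laptop.

## Known limitations

* No thermodynamic folding, ensembles or pair probabilities; the
  base-pair-maximization fold over-pairs relative to an energy model and
  should be read qualitatively.
* CAI without a curated highly-expressed reference set measures
  adaptation to the genome average, not to the translational optimum.
* The LSR functional form is a reasoned stand-in (see above); selection
  *mechanics* are exact, selection *weights* are the package's choice.
* No codon-pair bias, Shine–Dalgarno-like internal motif avoidance,
  repeat filters or mRNA-stability optimization; motif handling is
  report-only.
* The bundled usage tables are synthetic fixtures; conclusions about
  real organisms require their real tables.
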