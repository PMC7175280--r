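# Post-passes on a harmonization result: GC-content biasing and
# restriction-motif surveillance.

codon_gc <- function(codons) {
  vapply(strsplit(codons, ""), function(ch) sum(ch %in% c("G", "C")),
         integer(1))
}

# is `codon` (with host rcu `hrcu`) feasible at a position under the
# result's rule, given the position's native rcu?
rule_feasible <- function(rule, hrcu, native_rcu, tol, max_rcu) {
  switch(rule,
         FO = hrcu == max_rcu,
         DO = hrcu >= native_rcu - tol,
         NT = hrcu <= native_rcu,
         FT = TRUE)
}

#' Bias a harmonized sequence toward a GC-content target
#'
#' Greedy left-to-right pass over the ledger: at each codon position, the
#' synonyms whose host relative usage lies within `slack_points` of the
#' currently chosen codon's and that remain feasible under the result's
#' rule are considered, and the one minimizing the distance between the
#' whole-sequence GC content and `gc_target` is kept.  Translation is
#' preserved; swapped positions get rule note `"gc-bias"`.  The distance
#' `|GC - target|` never increases.  `slack_points = 0` disables the pass
#' (the result is returned unchanged).
#'
#' @param result A `harmonization_result`.
#' @param host The host [codon_usage_table()] used to produce it.
#' @param gc_target Target GC content, percent in (0, 100).
#' @param slack_points Host-rcu slack (percentage points) within which
#'   synonyms may be exchanged.
#' @return The updated `harmonization_result`.
#' @export
apply_gc_bias <- function(result, host, gc_target,
                          slack_points = result$config$gc_slack_points) {
  stopifnot(inherits(result, "harmonization_result"),
            inherits(host, "codon_usage_table"),
            gc_target > 0, gc_target < 100)
  if (slack_points <= 0) return(result)

  led <- result$ledger
  codons <- led$chosen_codon
  n_nt <- 3L * length(codons)
  gc_now <- sum(codon_gc(codons))
  tol <- result$config$do_tolerance_points

  for (i in seq_along(codons)) {
    if (led$amino_acid[i] == "*") next
    cand <- host_candidates(host, led$amino_acid[i])
    cur_rcu <- led$host_rcu[i]
    if (is.na(cur_rcu)) cur_rcu <- unname(host$rcu[codons[i]])
    keep <- abs(cand$host_rcu - cur_rcu) <= slack_points &
      vapply(cand$host_rcu, rule_feasible, logical(1), rule = result$rule,
             native_rcu = led$native_rcu[i], tol = tol,
             max_rcu = max(cand$host_rcu))
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0L) next
    base <- gc_now - codon_gc(codons[i])
    dist <- abs(100 * (base + codon_gc(cand$codon)) / n_nt - gc_target)
    cur_dist <- abs(100 * gc_now / n_nt - gc_target)
    ord <- order(dist, cand$codon)
    if (dist[ord[1L]] < cur_dist) {
      j <- ord[1L]
      gc_now <- base + codon_gc(cand$codon[j])
      codons[i] <- cand$codon[j]
      led$chosen_codon[i] <- cand$codon[j]
      led$host_rcu[i] <- cand$host_rcu[j]
      led$rule_note[i] <- paste0(led$rule_note[i], ";gc-bias")
    }
  }
  result$ledger <- led
  result$sequence <- paste(codons, collapse = "")
  result
}

#' Report occurrences of forbidden DNA motifs
#'
#' Exact-match scan on the given strand, counting overlapping and
#' self-similar matches at every start offset.  Report-only: no repair
#' is attempted.
#'
#' @param seq DNA string.
#' @param motifs Character vector of DNA motifs (optionally named).
#' @return Data frame with columns `motif` and `offset` (1-based
#'   nucleotide position of each match); zero rows when nothing matches.
#' @export
#' @examples
#' scan_forbidden_motifs("AAGGATCCTT", "GGATCC")  # offset 3
scan_forbidden_motifs <- function(seq,
                                  motifs = c(NcoI = "CCATGG",
                                             BamHI = "GGATCC")) {
  seq <- dna_normalize(seq)
  assert_dna(seq)
  subject <- Biostrings::DNAString(seq)
  hits <- lapply(motifs, function(m) {
    m <- dna_normalize(m)
    assert_dna(m, "motif")
    Biostrings::start(Biostrings::matchPattern(m, subject))
  })
  data.frame(motif = rep(unname(motifs), lengths(hits)),
             offset = as.integer(unlist(hits, use.names = FALSE)),
             stringsAsFactors = FALSE)
}
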