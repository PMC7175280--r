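# Shared helpers: fixture tables, toy-table builder, random genes and the
# brute-force folding oracle.

ecoli_tab <- function() load_usage_table(fixture_table_path("ecoli"),
                                         species_label = "ecoli")
mouse_tab <- function() load_usage_table(fixture_table_path("mouse"),
                                         species_label = "mouse")
burk_tab <- function() load_usage_table(fixture_table_path("burkholderia"),
                                        species_label = "burk")

# uniform base table (every synonym weight 1) with per-codon overrides
toy_table <- function(overrides = NULL, label = "toy") {
  freqs <- setNames(rep(1, 61), sense_codons())
  if (!is.null(overrides)) freqs[names(overrides)] <- overrides
  codon_usage_table(freqs, species_label = label)
}

# the codon with maximal / minimal frequency in its family (first on ties)
family_extreme_codon <- function(table, aa, which = c("max", "min")) {
  which <- match.arg(which)
  cods <- sort(codon_families()[[aa]])
  f <- table$freq[cods]
  cods[if (which == "max") which.max(f) else which.min(f)]
}

# random in-frame coding gene (no internal stop), returned as DNA string
random_gene <- function(n_codons, with_stop = TRUE) {
  cods <- sample(sense_codons(), n_codons, replace = TRUE)
  cods[1] <- "ATG"
  if (with_stop) cods <- c(cods, sample(stop_codons(), 1))
  paste(cods, collapse = "")
}

# independent %MinMax oracle: plain-loop evaluation of the window means
oracle_minmax <- function(codons, tab, w = 18) {
  fams <- codon_families()
  out <- numeric(length(codons) - w + 1)
  for (s in seq_along(out)) {
    win <- codons[s:(s + w - 1)]
    xa <- xmax <- xmin <- xavg <- 0
    for (cod in win) {
      syn <- fams[[genetic_code()[[cod]]]]
      xa <- xa + tab$freq[[cod]] / w
      xmax <- xmax + max(tab$freq[syn]) / w
      xmin <- xmin + min(tab$freq[syn]) / w
      xavg <- xavg + mean(tab$freq[syn]) / w
    }
    out[s] <- if (xa > xavg) 100 * (xa - xavg) / (xmax - xavg)
    else if (xa < xavg) -100 * (xavg - xa) / (xavg - xmin)
    else 0
  }
  out
}

# ---- independent folding oracle ----------------------------------------
# Exhaustive enumeration of non-crossing structures (no memoization, no
# shared code with fold_bpmax): returns the maximum base-pair count.

bf_pairable <- function(chars, allow_gu = TRUE) {
  chars <- gsub("T", "U", chars)
  ok <- c("AU", "UA", "GC", "CG", if (allow_gu) c("GU", "UG"))
  outer(chars, chars, FUN = function(a, b) paste0(a, b) %in% ok)
}

bf_max_pairs <- function(seq, min_loop = 3, allow_gu = TRUE) {
  chars <- strsplit(gsub("T", "U", toupper(seq)), "")[[1]]
  can <- bf_pairable(chars, allow_gu)
  g <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- g(i + 1L, j)                      # i unpaired
    for (k in (i + min_loop + 1L):j) {
      if (!can[i, k]) next
      best <- max(best, 1L + g(i + 1L, k - 1L) + g(k + 1L, j))
    }
    best
  }
  n <- length(chars)
  if (n < 2L) return(0L)
  g(1L, n)
}

# pair count and structural validity of a dot-bracket string
db_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  open <- integer(0)
  pairs <- NULL
  for (i in seq_along(chars)) {
    if (chars[i] == "(") open <- c(open, i)
    else if (chars[i] == ")") {
      stopifnot(length(open) > 0)
      pairs <- rbind(pairs, c(open[length(open)], i))
      open <- open[-length(open)]
    }
  }
  stopifnot(length(open) == 0)
  pairs
}
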