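# Sequence descriptors: %MinMax profile with a random reverse-translation
# null model, CAI, effective number of codons, ARCU, GC content and
# rare-codon annotation.

# per-codon usage frequency and the family max/min/average frequency at
# each position (stop codons excluded beforehand)
minmax_components <- function(codons, table) {
  fams <- codon_families()
  aa <- unname(genetic_code()[codons])
  fmax <- vapply(fams, function(c) max(table$freq[c]), numeric(1))
  fmin <- vapply(fams, function(c) min(table$freq[c]), numeric(1))
  favg <- vapply(fams, function(c) mean(table$freq[c]), numeric(1))
  list(actual = unname(table$freq[codons]),
       max = unname(fmax[aa]), min = unname(fmin[aa]),
       avg = unname(favg[aa]))
}

sliding_mean <- function(x, w) {
  cs <- c(0, cumsum(x))
  (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
}

#' %MinMax codon-optimality profile
#'
#' Slides a window (default 18 codons) along the coding sequence.  For
#' each window the mean usage frequency of the actual codons (X_actual)
#' is contrasted with the means of the maximal, minimal and average
#' synonymous frequencies available at those positions (X_max, X_min,
#' X_avg): the window scores `+100 (X_actual - X_avg) / (X_max - X_avg)`
#' when above average, `-100 (X_avg - X_actual) / (X_avg - X_min)` when
#' below, and 0 at the average.  +100 means a window of only the most
#' abundant codons, -100 a window of only the rarest.  Windows are
#' reported at their first codon; only full windows are emitted.  A
#' terminal stop codon is excluded from the profile.
#'
#' @param seq In-frame coding DNA string.
#' @param table Scoring [codon_usage_table()].
#' @param window_size Window length in codons; default 18.
#' @return Object of class `minmax_profile`: data frame `values` with
#'   columns `window_start`, `percent` (in \[-100, 100\]), plus
#'   `window_size` and `table_id`.
#' @export
percent_minmax <- function(seq, table, window_size = 18) {
  stopifnot(inherits(table, "codon_usage_table"))
  cds <- check_cds(seq)
  codons <- cds$codons
  if (cds$has_terminal_stop) codons <- codons[-length(codons)]
  L <- length(codons)
  if (L < window_size) {
    stop(sprintf("sequence has %d codons but the window needs %d",
                 L, window_size), call. = FALSE)
  }
  comp <- minmax_components(codons, table)
  xa <- sliding_mean(comp$actual, window_size)
  xmax <- sliding_mean(comp$max, window_size)
  xmin <- sliding_mean(comp$min, window_size)
  xavg <- sliding_mean(comp$avg, window_size)
  pct <- numeric(length(xa))
  up <- xa > xavg
  dn <- xa < xavg
  pct[up] <- 100 * (xa[up] - xavg[up]) / (xmax[up] - xavg[up])
  pct[dn] <- -100 * (xavg[dn] - xa[dn]) / (xavg[dn] - xmin[dn])
  structure(list(values = data.frame(window_start = seq_along(pct),
                                     percent = pct),
                 window_size = window_size,
                 table_id = table$species),
            class = "minmax_profile")
}

#' @export
print.minmax_profile <- function(x, ...) {
  cat(sprintf("%%MinMax profile: %d windows of %d codons (table %s)\n",
              nrow(x$values), x$window_size, x$table_id))
  cat(sprintf("range %.1f .. %.1f\n", min(x$values$percent),
              max(x$values$percent)))
  invisible(x)
}

#' Random reverse-translation null model for %MinMax
#'
#' Translates the sequence, then reverse-translates it `n_replicates`
#' times sampling each amino acid's codons with probability equal to
#' their per-amino-acid frequency in `table`, and returns the per-window
#' mean %MinMax across replicates.  Seeded and reproducible.
#'
#' @inheritParams percent_minmax
#' @param n_replicates Number of random reverse translations; default 100.
#' @param seed Integer seed (required).
#' @return Data frame `window_start`, `null_percent`.
#' @export
null_model_minmax <- function(seq, table, window_size = 18,
                              n_replicates = 100, seed) {
  stopifnot(n_replicates >= 1)
  if (missing(seed)) stop("null_model_minmax requires a seed", call. = FALSE)
  cds <- check_cds(seq)
  aa <- cds$aa
  if (cds$has_terminal_stop) aa <- aa[-length(aa)]
  fams <- codon_families()
  n_win <- length(aa) - window_size + 1L
  traces <- with_preserved_rng(seed, {
    vapply(seq_len(n_replicates), function(r) {
      cods <- vapply(aa, function(a) {
        cc <- fams[[a]]
        if (length(cc) == 1L) cc else
          sample(cc, 1L, prob = table$per_aa_freq[cc])
      }, character(1))
      percent_minmax(paste(cods, collapse = ""), table,
                     window_size)$values$percent
    }, numeric(n_win))
  })
  data.frame(window_start = seq_len(n_win),
             null_percent = rowMeans(matrix(traces, nrow = n_win)))
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean over codons of the relative-adaptiveness weight
#' `w = rcu / 100` under a reference usage table (ideally built from
#' highly expressed genes; the host table is a common stand-in).  Codons
#' of the single-codon families (Met ATG, Trp TGG) and stop codons are
#' excluded from the product.
#'
#' @param seq In-frame coding DNA string.
#' @param reference A [codon_usage_table()], or a named numeric codon ->
#'   w map (weights in (0, 1\]).
#' @param zero_weight What to do when an included codon has weight 0:
#'   `"error"` (default) or `"pseudo"` (substitute 0.5 / family size).
#' @return CAI in (0, 1\].
#' @export
cai <- function(seq, reference, zero_weight = c("error", "pseudo")) {
  zero_weight <- match.arg(zero_weight)
  if (inherits(reference, "codon_usage_table")) {
    w <- reference$rcu / 100
  } else {
    w <- unlist(reference)
    names(w) <- dna_normalize(names(w))
    missing <- setdiff(sense_codons(), names(w))
    if (length(missing)) {
      stop(sprintf("reference w map lacks codon(s): %s",
                   paste(head(missing, 5), collapse = ", ")), call. = FALSE)
    }
  }
  cds <- check_cds(seq)
  keep <- !(cds$codons %in% c("ATG", "TGG", stop_codons()))
  cods <- cds$codons[keep]
  if (length(cods) == 0L) {
    stop("no codons contribute to CAI (all Met/Trp/stop)", call. = FALSE)
  }
  wi <- unname(w[cods])
  if (any(wi == 0)) {
    if (zero_weight == "error") {
      stop(sprintf("codon %s has zero reference weight",
                   cods[which(wi == 0)[1]]), call. = FALSE)
    }
    deg <- family_degeneracy()[unname(genetic_code()[cods])]
    wi[wi == 0] <- 0.5 / deg[wi == 0]
  }
  exp(mean(log(wi)))
}

#' Effective number of codons (Nc)
#'
#' Wright-style bias statistic ranging from 20 (exactly one codon used
#' per amino acid) to 61 (perfectly uniform synonymous usage).  The
#' default plug-in estimator uses family homozygosity
#' `F = sum(p^2)` over the observed synonymous proportions, averages F
#' within each degeneracy class, and returns
#' `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` (the 2 counts Met and Trp);
#' with it the 20/61 bounds are attained exactly.  A bias-corrected
#' variant (`method = "wright"`, `F = (n sum(p^2) - 1) / (n - 1)`) is
#' offered; it requires at least two observations per contributing
#' family.  Degeneracy classes with no observed family are imputed from
#' F = 1 (maximal bias).  Stop codons are ignored.
#'
#' @param seq In-frame coding DNA string.
#' @param method `"plugin"` (default) or `"wright"`.
#' @param clamp Clamp the result to \[20, 61\]; default `TRUE`.
#' @return Effective number of codons.
#' @export
effective_number_of_codons <- function(seq, method = c("plugin", "wright"),
                                       clamp = TRUE) {
  method <- match.arg(method)
  cds <- check_cds(seq)
  cods <- cds$codons[cds$aa != "*"]
  if (length(cods) == 0L) stop("no sense codons in sequence", call. = FALSE)
  counts <- table(factor(cods, levels = sense_codons()))
  fams <- codon_families()
  deg <- family_degeneracy()

  fam_F <- vapply(names(fams), function(a) {
    nobs <- counts[fams[[a]]]
    n <- sum(nobs)
    if (n == 0L) return(NA_real_)
    p <- as.numeric(nobs) / n
    if (method == "plugin") sum(p^2)
    else if (n < 2L) NA_real_ else (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))

  class_F <- function(k) {
    f <- fam_F[deg == k & names(deg) != "M" & names(deg) != "W"]
    f <- f[!is.na(f)]
    if (length(f) == 0L) return(1)   # unobserved class: maximal bias
    mean(f)
  }
  nc <- 2 + 9 / class_F(2) + 1 / class_F(3) + 5 / class_F(4) + 3 / class_F(6)
  if (clamp) nc <- min(max(nc, 20), 61)
  nc
}

#' Average relative codon usage (ARCU)
#'
#' Arithmetic mean of the per-codon relative usage over the sequence
#' (terminal stop excluded).  With a [region_map()] each codon is scored
#' against its own segment's table.
#'
#' @param seq In-frame coding DNA string.
#' @param native A [codon_usage_table()] or [region_map()].
#' @return Percentage in \[0, 100\].
#' @export
arcu <- function(seq, native) {
  cds <- check_cds(seq)
  nat <- native_rcu_by_position(cds$codons, native)
  mean(nat$rcu[cds$aa != "*"])
}

#' GC content of a DNA sequence
#'
#' @param seq DNA string (strict ACGT alphabet; ambiguity codes are
#'   rejected).
#' @return Percentage of G+C, in \[0, 100\].
#' @export
#' @examples
#' gc_content("ATGC")  # 50
gc_content <- function(seq) {
  seq <- dna_normalize(seq)
  assert_dna(seq)
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  100 * (nchar(gsub("[AT]", "", seq))) / nchar(seq)
}

#' Annotate rare codons
#'
#' Flags every codon whose native relative usage is strictly below the
#' threshold (default 40 percent).  A terminal stop codon is never
#' flagged.
#'
#' @param seq In-frame coding DNA string.
#' @param native A [codon_usage_table()] or [region_map()].
#' @param threshold Rare threshold in relative-usage percentage points;
#'   strict `<` comparison.  Default 40.
#' @return Object of class `rare_codon_annotation`: `threshold` plus a
#'   data frame `positions` with columns `position`, `codon`,
#'   `native_rcu` (1-based codon indices).
#' @export
annotate_rare <- function(seq, native, threshold = 40) {
  cds <- check_cds(seq)
  nat <- native_rcu_by_position(cds$codons, native)
  sel <- which(!is.na(nat$rcu) & nat$rcu < threshold)
  structure(list(threshold = threshold,
                 positions = data.frame(position = sel,
                                        codon = cds$codons[sel],
                                        native_rcu = nat$rcu[sel])),
            class = "rare_codon_annotation")
}

#' @export
print.rare_codon_annotation <- function(x, ...) {
  cat(sprintf("rare codons (< %g%% native RCU): %d position(s)\n",
              x$threshold, nrow(x$positions)))
  invisible(x)
}

#' One-stop metric report for a coding sequence
#'
#' Computes CAI (against `reference`, defaulting to the host table),
#' effective number of codons, ARCU (against `native`, defaulting to the
#' host table), GC content and the rare-codon count.
#'
#' @param seq In-frame coding DNA string.
#' @param host Host [codon_usage_table()].
#' @param native Optional [codon_usage_table()] or [region_map()] for
#'   ARCU and rare-codon annotation; defaults to `host`.
#' @param reference Optional CAI reference (table or w map); defaults to
#'   `host`.
#' @param rare_threshold Rare-codon threshold (percent); default 40.
#' @param nc_method Estimator passed to [effective_number_of_codons()].
#' @return Object of class `metric_report` with fields `cai`, `nc`,
#'   `arcu`, `gc_percent`, `n_rare`, `n_codons` and provenance.
#' @export
metric_report <- function(seq, host, native = NULL, reference = NULL,
                          rare_threshold = 40,
                          nc_method = c("plugin", "wright")) {
  nc_method <- match.arg(nc_method)
  native <- native %||% host
  reference <- reference %||% host
  cds <- check_cds(seq)
  structure(list(cai = cai(seq, reference),
                 nc = effective_number_of_codons(seq, method = nc_method),
                 arcu = arcu(seq, native),
                 gc_percent = gc_content(dna_normalize(seq)),
                 n_rare = nrow(annotate_rare(seq, native,
                                             rare_threshold)$positions),
                 n_codons = length(cds$codons),
                 rare_threshold = rare_threshold,
                 nc_method = nc_method,
                 host_species = host$species),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("CAI %.3f | Nc %.1f | ARCU %.1f%% | GC %.1f%% | ",
                     "%d rare codon(s) of %d\n"),
              x$cai, x$nc, x$arcu, x$gc_percent, x$n_rare, x$n_codons))
  invisible(x)
}
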