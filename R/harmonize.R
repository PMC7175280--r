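# The four sequence-design engines.
#
# FO ("full optimization"): every codon becomes the host family maximum.
# DO: pick the host synonym closest in relative usage to the native
#     codon's, never dropping more than `do_tolerance_points` (default 5
#     percentage points) below it.
# NT ("no tolerance"): pick the host synonym with the closest relative
#     usage not exceeding the native codon's.
# FT ("full tolerance"): draw among all host synonyms according to a
#     likelihood-for-selection (LSR) distribution that favours candidates
#     whose relative usage is similar to the native codon's, via a
#     cumulative random walk (one uniform draw per codon position).
#
# All engines preserve the encoded protein exactly; a terminal stop codon
# is passed through verbatim.

#' Harmonization engine configuration
#'
#' @param do_tolerance_points DO rule: maximum number of relative-usage
#'   percentage points a chosen host codon may sit below the native
#'   codon's relative usage.  Default 5.
#' @param ft_seed Integer seed for the FT engine's per-codon draws.
#'   Required by [harmonize_ft()].
#' @param gc_target Optional GC-content target (percent, in (0, 100))
#'   consumed by [apply_gc_bias()].
#' @param gc_slack_points Relative-usage slack (points) within which
#'   [apply_gc_bias()] may swap synonyms; `0` disables the pass.
#' @param forbidden_motifs DNA motifs reported by
#'   [scan_forbidden_motifs()]; defaults to the NcoI and BamHI sites used
#'   for cloning.
#' @param rare_threshold_points Relative-usage percentage below which a
#'   codon counts as rare (strict inequality).  Default 40.
#' @return Object of class `harmonization_config`.
#' @export
harmonization_config <- function(do_tolerance_points = 5,
                                 ft_seed = NULL,
                                 gc_target = NULL,
                                 gc_slack_points = 5,
                                 forbidden_motifs = c(NcoI = "CCATGG",
                                                      BamHI = "GGATCC"),
                                 rare_threshold_points = 40) {
  stopifnot(do_tolerance_points >= 0)
  if (!is.null(gc_target)) {
    stopifnot(gc_target > 0, gc_target < 100)
  }
  structure(list(do_tolerance_points = do_tolerance_points,
                 ft_seed = ft_seed,
                 gc_target = gc_target,
                 gc_slack_points = gc_slack_points,
                 forbidden_motifs = forbidden_motifs,
                 rare_threshold_points = rare_threshold_points),
            class = "harmonization_config")
}

# Host candidate set for one amino acid: synonyms with their host rcu,
# zero-frequency codons dropped when a nonzero alternative exists (they
# are only ever emitted as a last resort, with a warning).
host_candidates <- function(host, aa) {
  cods <- codon_families()[[aa]]
  freq <- host$freq[cods]
  if (any(freq > 0) && any(freq == 0)) cods <- cods[freq > 0]
  data.frame(codon = cods, host_rcu = unname(host$rcu[cods]),
             stringsAsFactors = FALSE)
}

fmt_feasible <- function(cand) {
  paste(sprintf("%s:%g", cand$codon, cand$host_rcu), collapse = ";")
}

# deterministic pick: smallest |delta|, then highest host rcu, then
# lexicographically smallest codon
pick_closest <- function(cand, native_rcu) {
  d <- abs(cand$host_rcu - native_rcu)
  ord <- order(d, -cand$host_rcu, cand$codon)
  cand[ord[1L], , drop = FALSE]
}

choose_fo <- function(cand) {
  top <- cand[cand$host_rcu == max(cand$host_rcu), , drop = FALSE]
  top <- top[order(top$codon), , drop = FALSE]
  list(codon = top$codon[1L], host_rcu = top$host_rcu[1L],
       feasible = top, note = "fo")
}

choose_do <- function(cand, native_rcu, tol) {
  feas <- cand[cand$host_rcu >= native_rcu - tol, , drop = FALSE]
  # the host family maximum (rcu 100) is always feasible, so feas is
  # non-empty for any native_rcu <= 100 + tol
  sel <- pick_closest(feas, native_rcu)
  list(codon = sel$codon, host_rcu = sel$host_rcu, feasible = feas,
       note = "do")
}

choose_nt <- function(cand, native_rcu) {
  feas <- cand[cand$host_rcu <= native_rcu, , drop = FALSE]
  if (nrow(feas) == 0L) {
    # no host synonym at or below the native usage: take the closest
    # achievable from below, i.e. the minimal-rcu synonym
    ord <- order(cand$host_rcu, cand$codon)
    sel <- cand[ord[1L], , drop = FALSE]
    return(list(codon = sel$codon, host_rcu = sel$host_rcu,
                feasible = cand[0L, ], note = "nt-fallback"))
  }
  ord <- order(-feas$host_rcu, feas$codon)
  sel <- feas[ord[1L], , drop = FALSE]
  list(codon = sel$codon, host_rcu = sel$host_rcu, feasible = feas,
       note = "nt")
}

#' Likelihood-for-selection (LSR) distribution over host candidates
#'
#' Scores each candidate by how close its host relative usage is to the
#' native codon's: `s_i = max(100 - |host_rcu_i - native_rcu|, 1e-6)`,
#' normalised to sum to 1.  Candidates are returned sorted by decreasing
#' LSR (ties broken by codon string), the order in which the FT engine's
#' cumulative random walk visits them.
#'
#' The linear functional form is the package's own choice: it reproduces
#' the required ranking (closer relative usage, higher selection
#' likelihood) and is pluggable; the cumulative-draw mechanics are fixed.
#'
#' @param native_rcu Native relative usage (percent).
#' @param host_candidates Data frame with columns `codon`, `host_rcu`.
#' @return Data frame `codon`, `host_rcu`, `abs_delta`, `lsr`, sorted by
#'   decreasing `lsr`.
#' @export
#' @examples
#' compute_lsr(50, data.frame(codon = c("CTG", "TTA"),
#'                            host_rcu = c(50, 100)))
compute_lsr <- function(native_rcu, host_candidates) {
  stopifnot(nrow(host_candidates) >= 1L)
  d <- abs(host_candidates$host_rcu - native_rcu)
  s <- pmax(100 - d, 1e-6)
  lsr <- s / sum(s)
  out <- data.frame(codon = host_candidates$codon,
                    host_rcu = host_candidates$host_rcu,
                    abs_delta = d, lsr = lsr,
                    stringsAsFactors = FALSE)
  out[order(-out$lsr, out$codon), , drop = FALSE]
}

# one FT selection given a uniform draw u: walk candidates in descending
# LSR, return the first whose cumulative LSR exceeds u
lsr_select <- function(lsr_table, u) {
  idx <- findInterval(u, cumsum(lsr_table$lsr)) + 1L
  idx <- min(idx, nrow(lsr_table))  # guard against rounding at u ~ 1
  lsr_table[idx, , drop = FALSE]
}

# ---- shared engine driver ---------------------------------------------

harmonize_engine <- function(seq, native, host, rule, config) {
  stopifnot(inherits(host, "codon_usage_table"),
            inherits(config, "harmonization_config"))
  cds <- check_cds(seq, "input sequence")
  codons <- cds$codons
  n <- length(codons)
  sense <- which(cds$aa != "*")

  if (rule == "FO") {
    nat <- list(rcu = rep(NA_real_, n), table_id = rep(NA_character_, n),
                tables = list())
  } else {
    nat <- native_rcu_by_position(codons, native)
  }

  chosen <- codons
  ledger <- data.frame(position = seq_len(n), amino_acid = cds$aa,
                       native_codon = codons, native_rcu = nat$rcu,
                       chosen_codon = codons,
                       host_rcu = NA_real_, feasible_set = "",
                       rule_note = "", stringsAsFactors = FALSE)
  if (any(cds$aa == "*")) {
    ledger$rule_note[cds$aa == "*"] <- "stop-preserved"
  }

  u <- NULL
  if (rule == "FT") {
    if (is.null(config$ft_seed)) {
      stop("the FT engine requires config$ft_seed", call. = FALSE)
    }
    u <- with_preserved_rng(config$ft_seed, runif(n))
  }

  # selections depend only on (amino acid | native codon, segment table),
  # so cache them
  cache <- new.env(parent = emptyenv())
  emitted_zero <- character(0)
  for (i in sense) {
    aa <- cds$aa[i]
    key <- paste(rule, nat$table_id[i], codons[i], sep = "|")
    if (rule == "FT") {
      lk <- paste("lsr", nat$table_id[i], codons[i], sep = "|")
      lt <- cache[[lk]]
      if (is.null(lt)) {
        lt <- compute_lsr(nat$rcu[i], host_candidates(host, aa))
        cache[[lk]] <- lt
      }
      selrow <- lsr_select(lt, u[i])
      sel <- list(codon = selrow$codon, host_rcu = selrow$host_rcu,
                  feasible = lt[, c("codon", "host_rcu")], note = "ft")
    } else {
      sel <- cache[[key]]
      if (is.null(sel)) {
        cand <- host_candidates(host, aa)
        sel <- switch(rule,
                      FO = choose_fo(cand),
                      DO = choose_do(cand, nat$rcu[i],
                                     config$do_tolerance_points),
                      NT = choose_nt(cand, nat$rcu[i]))
        cache[[key]] <- sel
      }
    }
    chosen[i] <- sel$codon
    ledger$chosen_codon[i] <- sel$codon
    ledger$host_rcu[i] <- sel$host_rcu
    ledger$feasible_set[i] <- fmt_feasible(sel$feasible)
    ledger$rule_note[i] <- sel$note
    if (host$freq[[sel$codon]] == 0) emitted_zero <- c(emitted_zero, sel$codon)
  }
  if (length(emitted_zero)) {
    warning(sprintf("emitted zero-frequency host codon(s) %s (only feasible choice)",
                    paste(unique(emitted_zero), collapse = ", ")),
            call. = FALSE)
  }

  out <- paste(chosen, collapse = "")
  stopifnot(translate_cds(out) == paste(cds$aa, collapse = ""))
  structure(list(sequence = out,
                 ledger = ledger,
                 rule = rule,
                 config = config,
                 host_species = host$species,
                 native_table_ids = unique(nat$table_id),
                 seed = if (rule == "FT") config$ft_seed else NULL),
            class = "harmonization_result")
}

#' @export
print.harmonization_result <- function(x, ...) {
  n <- nrow(x$ledger)
  changed <- sum(x$ledger$chosen_codon != x$ledger$native_codon)
  cat(sprintf("%s harmonization: %d codons, %d substituted, host %s\n",
              x$rule, n, changed, x$host_species))
  invisible(x)
}

#' Fully codon-optimize a coding sequence
#'
#' Replaces every codon with the host synonym of maximal relative usage
#' (rcu 100); ties are broken lexicographically.  A terminal stop codon
#' is preserved verbatim.
#'
#' @param seq In-frame coding DNA string (no internal stops).
#' @param host A [codon_usage_table()] for the expression host.
#' @param config A [harmonization_config()].
#' @return A `harmonization_result`: `sequence` plus a per-codon `ledger`
#'   (position, amino acid, native codon/rcu, chosen codon, host rcu,
#'   feasible set, rule note) and provenance fields.
#' @export
harmonize_fo <- function(seq, host, config = harmonization_config()) {
  harmonize_engine(seq, native = NULL, host = host, rule = "FO",
                   config = config)
}

#' Harmonize with the 5-point deoptimization (DO) rule
#'
#' For each codon, the native relative usage is looked up in that codon's
#' segment table; host synonyms whose relative usage falls more than
#' `do_tolerance_points` (default 5) percentage points below it are
#' excluded, and the closest remaining candidate by absolute difference
#' is chosen (ties: higher host rcu, then lexicographically smallest
#' codon).  A native family maximum (rcu 100) therefore always maps to
#' the host family maximum.
#'
#' @inheritParams harmonize_fo
#' @param native A [codon_usage_table()] (single-species gene) or a
#'   [region_map()] (chimeric gene) giving native usage per codon.
#' @return A `harmonization_result`; see [harmonize_fo()].
#' @export
harmonize_do <- function(seq, native, host,
                         config = harmonization_config()) {
  harmonize_engine(seq, native, host, "DO", config)
}

#' Harmonize with the no-tolerance (NT) rule
#'
#' For each codon, only host synonyms whose relative usage does not
#' exceed the native codon's are feasible, and the one closest from
#' below (maximal feasible host rcu) is chosen.  When no host synonym
#' sits at or below the native usage, the minimal-rcu host synonym is
#' emitted and the ledger records `nt-fallback`.
#'
#' @inheritParams harmonize_do
#' @return A `harmonization_result`; see [harmonize_fo()].
#' @export
harmonize_nt <- function(seq, native, host,
                         config = harmonization_config()) {
  harmonize_engine(seq, native, host, "NT", config)
}

#' Harmonize with the full-tolerance (FT) stochastic rule
#'
#' Every host synonym is a candidate; each is assigned a likelihood for
#' selection (LSR, see [compute_lsr()]) that decreases with the absolute
#' difference between host and native relative usage.  Per codon
#' position, a uniform number u in \[0, 1) is drawn and candidates are
#' walked in descending LSR order, accumulating their LSR values; the
#' first candidate whose cumulative LSR exceeds u is selected.  One draw
#' is consumed per codon position in sequence order, so runs are
#' bit-reproducible given `config$ft_seed`.
#'
#' @inheritParams harmonize_do
#' @return A `harmonization_result`; see [harmonize_fo()].
#' @export
harmonize_ft <- function(seq, native, host,
                         config = harmonization_config(ft_seed = 1L)) {
  harmonize_engine(seq, native, host, "FT", config)
}

# run expr under a temporary seed without disturbing the caller's RNG
with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
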