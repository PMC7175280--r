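# Codon usage tables: parsing, validation and derived statistics.
#
# A codon_usage_table carries raw frequencies (counts or per-1000 values;
# the scale is irrelevant to every derived quantity), the relative codon
# usage (rcu, a.k.a. relative adaptiveness: percentage of the most-used
# synonym, 100 = family maximum) and the per-amino-acid frequency
# (fraction among synonyms, summing to 1 within each family).

#' Construct a codon usage table
#'
#' Builds a validated usage table from a named codon -> number map.  All
#' 61 sense codons must be present with nonnegative values; stop codons
#' are optional and, when present, form their own normalization family.
#' Relative codon usage (`rcu`, percent of the family maximum; the most
#' abundant synonym scores 100, ties all score 100) and per-amino-acid
#' frequencies (`per_aa_freq`, summing to 1 within each family) are
#' derived on construction.
#'
#' @param freqs Named numeric vector or list: codon (DNA or RNA alphabet,
#'   any case) -> nonnegative count or frequency.
#' @param species_label Free-text label recorded in the table.
#' @param source Optional free-text provenance note.
#' @return An object of class `codon_usage_table` with elements
#'   `species`, `freq`, `rcu`, `per_aa_freq`, `has_stops`, `source`.
#' @export
#' @examples
#' leu <- c(CTG = 50, TTA = 13, TTG = 13, CTT = 10, CTC = 10, CTA = 4)
#' base <- setNames(rep(1, 61), sense_codons())
#' base[names(leu)] <- leu
#' tab <- codon_usage_table(base, "toy")
#' relative_usage(tab, "TTA")  # 26
codon_usage_table <- function(freqs, species_label = "unknown",
                              source = NULL) {
  freqs <- unlist(freqs)
  if (is.null(names(freqs)) || any(names(freqs) == "")) {
    stop("usage table input must be a named codon -> number map",
         call. = FALSE)
  }
  names(freqs) <- dna_normalize(names(freqs))
  known <- names(genetic_code())
  bad <- setdiff(names(freqs), known)
  if (length(bad)) {
    stop(sprintf("unknown codon key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(names(freqs))) {
    stop("duplicated codon key(s) in usage table", call. = FALSE)
  }
  if (any(!is.finite(freqs)) || any(freqs < 0)) {
    stop("usage values must be finite and nonnegative", call. = FALSE)
  }
  missing_sense <- setdiff(sense_codons(), names(freqs))
  if (length(missing_sense)) {
    stop(sprintf("missing sense codon(s): %s",
                 paste(missing_sense, collapse = ", ")), call. = FALSE)
  }
  has_stops <- all(stop_codons() %in% names(freqs))

  fams <- codon_families()
  if (has_stops) fams <- c(fams, list(`*` = stop_codons()))
  rcu <- numeric(0)
  per_aa <- numeric(0)
  for (aa in names(fams)) {
    f <- freqs[fams[[aa]]]
    tot <- sum(f)
    if (tot == 0) {
      stop(sprintf("all-zero codon family for amino acid '%s'", aa),
           call. = FALSE)
    }
    rcu <- c(rcu, 100 * (f / max(f)))  # f/max first: family max is exactly 100
    per_aa <- c(per_aa, f / tot)
  }
  structure(
    list(species = species_label,
         freq = freqs[c(sense_codons(), if (has_stops) stop_codons())],
         rcu = rcu,
         per_aa_freq = per_aa,
         has_stops = has_stops,
         source = source),
    class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat(sprintf("codon usage table: %s (%d codons%s)\n", x$species,
              length(x$freq),
              if (x$has_stops) ", incl. stops" else ", no stops"))
  if (!is.null(x$source)) cat("source:", x$source, "\n")
  invisible(x)
}

#' Load a codon usage table from a file
#'
#' Two dialects are supported.  `"kazusa"` parses the whitespace grammar
#' of public codon-usage databases, `CODON freq (count)` repeated several
#' times per line, accepting RNA (U) or DNA (T) codons; the frequency
#' field is used and the count, when present, is ignored.  `"tsv"` parses
#' a simple two-column `codon<TAB>count` file without a header (lines
#' starting with `#` are skipped).  The internal representation is always
#' DNA.
#'
#' @param source Path to a table file, or a named codon -> number map
#'   (passed straight to [codon_usage_table()]).
#' @param dialect `"kazusa"` or `"tsv"`.
#' @param species_label Label stored in the table; defaults to the file
#'   name.
#' @return A [codon_usage_table()].
#' @export
load_usage_table <- function(source, dialect = c("kazusa", "tsv"),
                             species_label = NULL) {
  if (!is.character(source) || length(source) != 1L) {
    return(codon_usage_table(source,
                             species_label = species_label %||% "in-memory"))
  }
  dialect <- match.arg(dialect)
  if (!file.exists(source)) {
    stop(sprintf("usage table file not found: %s", source), call. = FALSE)
  }
  label <- species_label %||% basename(source)
  lines <- readLines(source, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  if (dialect == "kazusa") {
    txt <- paste(lines, collapse = " ")
    m <- gregexpr("([ACGTUacgtu]{3})\\s+([0-9]*\\.?[0-9]+)(\\s*\\(\\s*[0-9]+\\s*\\))?",
                  txt, perl = TRUE)
    hits <- regmatches(txt, m)[[1]]
    if (!length(hits)) {
      stop(sprintf("no 'CODON freq (count)' entries found in %s", source),
           call. = FALSE)
    }
    codons <- toupper(sub("^([ACGTUacgtu]{3}).*", "\\1", hits))
    freqs <- as.numeric(sub("^[ACGTUacgtu]{3}\\s+([0-9]*\\.?[0-9]+).*",
                            "\\1", hits))
    vals <- setNames(freqs, codons)
  } else {
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2L)) {
      stop(sprintf("malformed TSV line in %s (expected codon<TAB>count)",
                   source), call. = FALSE)
    }
    codons <- toupper(trimws(vapply(parts, `[[`, "", 1L)))
    freqs <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    if (anyNA(freqs)) {
      stop(sprintf("non-numeric count in %s", source), call. = FALSE)
    }
    vals <- setNames(freqs, codons)
  }
  codon_usage_table(vals, species_label = label, source = source)
}

#' Relative codon usage of one codon
#'
#' Returns the codon's usage frequency as a percentage of the most-used
#' synonymous codon in the table (100 = family maximum).
#'
#' @param table A [codon_usage_table()].
#' @param codon Codon string (DNA or RNA alphabet).
#' @param allow_stop Permit querying a stop codon (requires a table that
#'   includes stops); default `FALSE`.
#' @return Percentage in \[0, 100\].
#' @export
relative_usage <- function(table, codon, allow_stop = FALSE) {
  stopifnot(inherits(table, "codon_usage_table"))
  codon <- dna_normalize(codon)
  if (!codon %in% names(genetic_code())) {
    stop(sprintf("'%s' is not a codon", codon), call. = FALSE)
  }
  if (codon %in% stop_codons()) {
    if (!allow_stop) {
      stop(sprintf("'%s' is a stop codon; set allow_stop = TRUE", codon),
           call. = FALSE)
    }
    if (!table$has_stops) {
      stop("table does not include stop codons", call. = FALSE)
    }
  }
  unname(table$rcu[codon])
}

#' Paths to the bundled fixture usage tables
#'
#' The package bundles three clearly synthetic usage tables (an E. coli
#' -like host, a mouse-like and a Burkholderia-like native table) so the
#' whole workbench is exercisable without downloads.  Their values are
#' plausible stand-ins, not authoritative measurements.
#'
#' @param which `"ecoli"`, `"mouse"` or `"burkholderia"`.
#' @return Path to the bundled Kazusa-format file.
#' @export
fixture_table_path <- function(which = c("ecoli", "mouse", "burkholderia")) {
  which <- match.arg(which)
  fn <- c(ecoli = "ecoli_like_synthetic.kazusa.txt",
          mouse = "mouse_like_synthetic.kazusa.txt",
          burkholderia = "burkholderia_like_synthetic.kazusa.txt")[[which]]
  system.file("extdata", fn, package = "codonharmony", mustWork = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
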