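# Standard genetic code bookkeeping shared by every module.  Codons are
# uppercase DNA triplets; stop codons translate to the sentinel "*".

.codon_cache <- new.env(parent = emptyenv())

#' The standard genetic code as a named character vector
#'
#' Codon (uppercase DNA) -> one-letter amino acid; stop codons map to
#' `"*"`.  Taken from the standard code (translation table 1).
#'
#' @return Named character vector of length 64.
#' @export
#' @examples
#' genetic_code()[["ATG"]]
genetic_code <- function() {
  if (is.null(.codon_cache$code)) {
    gc <- Biostrings::GENETIC_CODE
    .codon_cache$code <- setNames(as.character(gc), names(gc))
  }
  .codon_cache$code
}

#' Sense and stop codons of the standard code
#'
#' @return Character vector of 61 sense codons (`sense_codons`) or the 3
#'   stop codons (`stop_codons`).
#' @export
sense_codons <- function() {
  code <- genetic_code()
  names(code)[code != "*"]
}

#' @rdname sense_codons
#' @export
stop_codons <- function() {
  code <- genetic_code()
  names(code)[code == "*"]
}

#' Synonymous-codon families of the standard code
#'
#' Groups the 61 sense codons by encoded amino acid.  Under the standard
#' code this yields 2 single-codon families (Met, Trp), 9 two-fold, 1
#' three-fold (Ile), 5 four-fold and 3 six-fold families.
#'
#' @return Named list, one character vector of codons per amino acid.
#' @export
codon_families <- function() {
  if (is.null(.codon_cache$families)) {
    code <- genetic_code()
    sense <- code[code != "*"]
    .codon_cache$families <- split(names(sense), unname(sense))
  }
  .codon_cache$families
}

# degeneracy class (family size) per amino acid, e.g. L -> 6
family_degeneracy <- function() {
  vapply(codon_families(), length, integer(1))
}

# ---- sequence helpers -------------------------------------------------

# Uppercase and convert RNA to DNA alphabet. Returns the string; callers
# that must report the U -> T conversion check beforehand.
dna_normalize <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

# error if x contains anything outside ACGT; `what` names the offender
assert_dna <- function(x, what = "sequence") {
  bad <- regexpr("[^ACGT]", x)
  if (bad > 0) {
    stop(sprintf("%s contains non-ACGT character '%s' at position %d",
                 what, substr(x, bad, bad), bad), call. = FALSE)
  }
  invisible(x)
}

# split an in-frame coding sequence into codons
split_codons <- function(seq) {
  if (nchar(seq) %% 3L != 0L) {
    stop(sprintf("sequence length %d is not divisible by 3", nchar(seq)),
         call. = FALSE)
  }
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate an in-frame coding DNA sequence
#'
#' @param seq In-frame coding DNA string (length divisible by 3).
#' @return Single string of one-letter amino acids, `"*"` for stops.
#' @export
#' @examples
#' translate_cds("ATGAAATAA")
translate_cds <- function(seq) {
  seq <- dna_normalize(seq)
  assert_dna(seq)
  paste(genetic_code()[split_codons(seq)], collapse = "")
}

# Validate a coding sequence for harmonization/diagnostics: in frame, DNA
# alphabet, no internal stop.  Returns list(codons, aa, has_terminal_stop).
check_cds <- function(seq, what = "sequence") {
  seq <- dna_normalize(seq)
  assert_dna(seq, what)
  codons <- split_codons(seq)
  if (length(codons) == 0L) stop(sprintf("%s is empty", what), call. = FALSE)
  aa <- unname(genetic_code()[codons])
  internal <- which(aa == "*")
  internal <- internal[internal < length(codons)]
  if (length(internal)) {
    stop(sprintf("internal stop codon %s at codon position %d in %s",
                 codons[internal[1]], internal[1], what), call. = FALSE)
  }
  list(codons = codons, aa = aa,
       has_terminal_stop = aa[length(aa)] == "*")
}
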