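# Translation-initiation window analysis: assemble the vector 5' context
# through the +8 coding nucleotide, attach a secondary structure (either
# an imported RNAfold dot-bracket or a base-pair-maximization fold), and
# report whether the ribosome-binding site is occluded by pairing.

#' Assemble a 5' translation-initiation window
#'
#' Concatenates the vector 5' context (positions -N ... -1) with the
#' first `coding_extent` nucleotides of the CDS (+1 ... +8 by default,
#' the span of the ribosomal footprint past the start codon) and locates
#' the ribosome-binding-site motif in the upstream part by exact search
#' (rightmost match when several; all matches are recorded).
#'
#' @param vector_utr DNA string of the vector 5' context.
#' @param cds Coding sequence (DNA); should begin with a start codon
#'   (a warning is given if it is not ATG).
#' @param coding_extent Number of CDS nucleotides included; default 8.
#' @param rbs_motif RBS motif searched in the upstream part; default
#'   `AGGAGA`.
#' @return Object of class `five_prime_window`: `upstream`,
#'   `coding_prefix`, `window`, `rbs_span` (1-based \[start, end\] within
#'   the window), `rbs_matches` (all match starts), `structure` (`NULL`
#'   until folded or imported), `pairing_count`, `rbs_paired_fraction`.
#' @export
build_window <- function(vector_utr, cds, coding_extent = 8,
                         rbs_motif = "AGGAGA") {
  vector_utr <- dna_normalize(vector_utr)
  cds <- dna_normalize(cds)
  assert_dna(vector_utr, "vector UTR")
  assert_dna(cds, "CDS")
  if (nchar(cds) < coding_extent) {
    stop(sprintf("CDS has %d nt but coding_extent = %d needs more",
                 nchar(cds), coding_extent), call. = FALSE)
  }
  if (substr(cds, 1, 3) != "ATG") {
    warning(sprintf("CDS starts with %s, not ATG", substr(cds, 1, 3)),
            call. = FALSE)
  }
  starts <- scan_forbidden_motifs(vector_utr, rbs_motif)$offset
  if (length(starts) == 0L) {
    stop(sprintf("RBS motif %s not found in the vector UTR", rbs_motif),
         call. = FALSE)
  }
  rbs_start <- max(starts)
  prefix <- substr(cds, 1, coding_extent)
  structure(list(upstream = vector_utr,
                 coding_prefix = prefix,
                 window = paste0(vector_utr, prefix),
                 rbs_motif = rbs_motif,
                 rbs_span = c(rbs_start, rbs_start + nchar(rbs_motif) - 1L),
                 rbs_matches = starts,
                 structure = NULL,
                 energy = NULL,
                 pairing_count = NA_integer_,
                 rbs_paired_fraction = NA_real_),
            class = "five_prime_window")
}

#' @export
print.five_prime_window <- function(x, ...) {
  cat(sprintf("5' window: %d nt (-%d..+%d), RBS %s at %d-%d\n",
              nchar(x$window), nchar(x$upstream), nchar(x$coding_prefix),
              x$rbs_motif, x$rbs_span[1], x$rbs_span[2]))
  if (!is.null(x$structure)) {
    cat(sprintf("structure: %d pair(s), RBS paired fraction %.2f\n",
                x$pairing_count, x$rbs_paired_fraction))
  }
  invisible(x)
}

# which pairing alphabet: Watson-Crick plus optional G:U wobble (RNA view)
pairable_matrix <- function(chars, allow_gu = TRUE) {
  chars <- gsub("T", "U", chars)
  pairs <- c("AU", "UA", "GC", "CG")
  if (allow_gu) pairs <- c(pairs, "GU", "UG")
  outer(chars, chars, FUN = function(a, b) paste0(a, b) %in% pairs)
}

#' Maximum-base-pair fold of a short RNA window
#'
#' Nussinov-style dynamic program maximizing the number of Watson-Crick
#' (plus, optionally, G:U wobble) base pairs, with a minimum hairpin loop
#' of `min_loop` unpaired bases.  This is a deterministic, qualitative
#' stand-in for thermodynamic folding: it reports pairing potential, not
#' free energies.  Traceback is deterministic (a position pairs with its
#' leftmost optimal partner), so identical inputs give identical
#' structures.
#'
#' @param window DNA or RNA string.
#' @param min_loop Minimum number of unpaired bases inside a hairpin
#'   loop; default 3.
#' @param allow_gu Allow G:U wobble pairs; default `TRUE`.
#' @return Balanced dot-bracket string of the same length.
#' @export
#' @examples
#' fold_bpmax("GGGAAACCC")  # "(((...)))"
fold_bpmax <- function(window, min_loop = 3, allow_gu = TRUE) {
  window <- dna_normalize(window)
  assert_dna(window, "window")
  n <- nchar(window)
  if (n == 0L) stop("empty window", call. = FALSE)
  chars <- strsplit(window, "")[[1]]
  can <- pairable_matrix(chars, allow_gu)

  # N[i,j] = max pairs on the subsequence i..j
  N <- matrix(0L, n, n)
  if (n > min_loop + 1L) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in 1L:(n - span)) {
        j <- i + span
        best <- N[i, j - 1L]                       # j unpaired
        ks <- i:(j - min_loop - 1L)
        for (k in ks) {
          if (!can[k, j]) next
          left <- if (k > i) N[i, k - 1L] else 0L
          mid <- if (k + 1L <= j - 1L) N[k + 1L, j - 1L] else 0L
          cand <- left + mid + 1L
          if (cand > best) best <- cand
        }
        N[i, j] <- best
      }
    }
  }

  db <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j || j - i <= min_loop) next
    paired <- FALSE
    # prefer pairing j with its leftmost optimal partner
    for (k in i:(j - min_loop - 1L)) {
      if (!can[k, j]) next
      left <- if (k > i) N[i, k - 1L] else 0L
      mid <- if (k + 1L <= j - 1L) N[k + 1L, j - 1L] else 0L
      if (left + mid + 1L == N[i, j]) {
        db[k] <- "("
        db[j] <- ")"
        if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
        if (k + 1L <= j - 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
        paired <- TRUE
        break
      }
    }
    if (!paired) stack[[length(stack) + 1L]] <- c(i, j - 1L)
  }
  paste(db, collapse = "")
}

# dot-bracket utilities ---------------------------------------------------

parse_dot_bracket <- function(db) {
  chars <- strsplit(db, "")[[1]]
  if (any(!chars %in% c(".", "(", ")"))) {
    stop("structure contains characters other than '.', '(' and ')'",
         call. = FALSE)
  }
  open <- integer(0)
  partner <- rep(NA_integer_, length(chars))
  for (i in seq_along(chars)) {
    if (chars[i] == "(") open <- c(open, i)
    else if (chars[i] == ")") {
      if (length(open) == 0L) {
        stop(sprintf("unbalanced ')' at position %d", i), call. = FALSE)
      }
      j <- open[length(open)]
      open <- open[-length(open)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(open)) {
    stop(sprintf("unbalanced '(' at position %d", open[1]), call. = FALSE)
  }
  partner
}

attach_structure <- function(fpw, db, energy = NULL) {
  if (nchar(db) != nchar(fpw$window)) {
    stop(sprintf("structure length %d does not match window length %d",
                 nchar(db), nchar(fpw$window)), call. = FALSE)
  }
  partner <- parse_dot_bracket(db)
  fpw$structure <- db
  fpw$energy <- energy
  fpw$pairing_count <- sum(!is.na(partner)) %/% 2L
  rbs <- fpw$rbs_span[1]:fpw$rbs_span[2]
  fpw$rbs_paired_fraction <- mean(!is.na(partner[rbs]))
  fpw
}

#' Fold a 5' window in place
#'
#' Convenience wrapper: runs [fold_bpmax()] on the window and attaches
#' the resulting structure.
#'
#' @param fpw A [build_window()] result.
#' @inheritParams fold_bpmax
#' @return The `five_prime_window` with structure attached.
#' @export
fold_window <- function(fpw, min_loop = 3, allow_gu = TRUE) {
  stopifnot(inherits(fpw, "five_prime_window"))
  attach_structure(fpw, fold_bpmax(fpw$window, min_loop, allow_gu))
}

#' Import an externally computed structure (Vienna dialect)
#'
#' Parses RNAfold-style output: an optional `>name` header, a sequence
#' line, and a structure line consisting of dots and brackets with an
#' optional trailing free energy in parentheses, e.g.
#' `"...((...))... (-1.20)"`.  The structure must match the window
#' length and be balanced; the energy, when present, is stored as an
#' annotation only (never recomputed).
#'
#' @param fpw A [build_window()] result.
#' @param text Character vector of lines, or the path to a file.
#' @return The `five_prime_window` with structure (and energy
#'   annotation) attached.
#' @export
import_structure <- function(fpw, text) {
  stopifnot(inherits(fpw, "five_prime_window"))
  if (length(text) == 1L && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  lines <- trimws(text)
  lines <- lines[nzchar(lines) & !startsWith(lines, ">")]
  struct_line <- grep("^[.()]+(\\s+\\(\\s*-?[0-9]+\\.?[0-9]*\\s*\\))?$",
                      lines, value = TRUE)
  if (length(struct_line) == 0L) {
    stop("no dot-bracket structure line found", call. = FALSE)
  }
  struct_line <- struct_line[1]
  db <- sub("\\s.*$", "", struct_line)
  energy <- NULL
  em <- regmatches(struct_line,
                   regexpr("\\s\\(\\s*-?[0-9]+\\.?[0-9]*\\s*\\)$",
                           struct_line))
  if (length(em)) {
    energy <- as.numeric(gsub("[()\\s]", "", em, perl = TRUE))
  }
  attach_structure(fpw, db, energy)
}

#' Ribosome-binding-site occlusion verdict
#'
#' The RBS is called `occluded` when at least one of its nucleotides is
#' base-paired in the attached structure, `free` otherwise; the paired
#' fraction (paired RBS nt / motif length) is reported alongside.
#'
#' @param fpw A `five_prime_window` with a structure attached.
#' @return List with `verdict` (`"free"` or `"occluded"`) and
#'   `rbs_paired_fraction`.
#' @export
rbs_occlusion <- function(fpw) {
  stopifnot(inherits(fpw, "five_prime_window"))
  if (is.null(fpw$structure)) {
    stop("no structure attached; fold_window() or import_structure() first",
         call. = FALSE)
  }
  list(verdict = if (fpw$rbs_paired_fraction > 0) "occluded" else "free",
       rbs_paired_fraction = fpw$rbs_paired_fraction)
}
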