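# File I/O and the synthetic-data generator that makes every module
# testable without downloads.

#' Read / write nucleotide FASTA
#'
#' `read_fasta()` reads a FASTA file, uppercases the sequences, converts
#' RNA (U) to DNA (T) with a message, and rejects any non-ACGT character
#' (ambiguity codes included) naming the record and offset.
#' `write_fasta()` writes a named character vector, wrapping at 60
#' columns.  A write -> read round trip is the identity.
#'
#' @param path File path.
#' @return `read_fasta()`: named character vector of DNA sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(grepl("U", seqs, fixed = TRUE))) {
    message("RNA alphabet detected; converting U -> T")
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
  }
  for (i in seq_along(seqs)) {
    assert_dna(seqs[[i]], sprintf("record '%s'", names(seqs)[i]))
  }
  seqs
}

#' @param records Named character vector of DNA sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.character(records), !is.null(names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Generate a synthetic coding gene with a known rare-codon truth ledger
#'
#' Emulates a chimeric gene with mixed optimal/rare codon composition:
#' after a fixed ATG start, each interior codon is drawn from its
#' segment table's rare pool (sense codons with relative usage below
#' `rare_threshold`) with probability `fraction_rare`, otherwise from the
#' non-rare pool, sampling within the pool by usage frequency; a terminal
#' stop (the segment table's most frequent stop, or TAA) is appended.
#' The gene is in frame, free of internal stops, and ships with a
#' per-position truth ledger.
#'
#' @param n_codons Number of codons excluding the terminal stop.
#' @param fraction_rare Target fraction of interior codons drawn from the
#'   rare pool, in \[0, 1\].
#' @param native A [codon_usage_table()] or [region_map()] covering
#'   `n_codons` codons.
#' @param seed Integer seed (required; the generator is reproducible).
#' @param rare_threshold Rare threshold (percent, strict `<`); default 40.
#' @return List with `sequence` (DNA string, `3 * (n_codons + 1)` nt)
#'   and `ledger` (data frame: `position`, `codon`, `amino_acid`,
#'   `native_rcu`, `sampled_rare`, `table_id`; the forced start codon has
#'   `sampled_rare = NA`), plus `seed` and `fraction_rare`.
#' @export
generate_synthetic_gene <- function(n_codons, fraction_rare, native, seed,
                                    rare_threshold = 40) {
  stopifnot(n_codons >= 2, fraction_rare >= 0, fraction_rare <= 1)
  if (missing(seed)) stop("generate_synthetic_gene requires a seed",
                          call. = FALSE)
  reg <- resolve_regions(native, n_codons)

  pools <- lapply(reg$tables, function(tab) {
    sc <- sense_codons()
    rare <- sc[tab$rcu[sc] < rare_threshold]
    common <- sc[tab$rcu[sc] >= rare_threshold]
    list(rare = rare, common = common, tab = tab)
  })
  if (fraction_rare > 0) {
    empty <- names(pools)[vapply(pools, function(p) length(p$rare) == 0L,
                                 logical(1))]
    empty <- intersect(empty, unique(reg$table_id))
    if (length(empty)) {
      stop(sprintf("table(s) %s have no codon below %g%% RCU; fraction_rare > 0 is infeasible",
                   paste(empty, collapse = ", "), rare_threshold),
           call. = FALSE)
    }
  }

  codons <- character(n_codons)
  sampled_rare <- rep(NA, n_codons)
  codons[1] <- "ATG"
  with_preserved_rng(seed, {
    draw_rare <- runif(n_codons) < fraction_rare
    for (i in 2:n_codons) {
      p <- pools[[reg$table_id[i]]]
      pool <- if (draw_rare[i]) p$rare else p$common
      w <- p$tab$freq[pool]
      if (all(w == 0)) w <- rep(1, length(pool))
      codons[i] <- if (length(pool) == 1L) pool else
        sample(pool, 1L, prob = w)
      sampled_rare[i] <- draw_rare[i]
    }
  })

  last_tab <- reg$tables[[reg$table_id[n_codons]]]
  stop_codon <- if (last_tab$has_stops) {
    names(which.max(last_tab$freq[stop_codons()]))
  } else "TAA"

  nat <- native_rcu_by_position(codons, native)
  list(sequence = paste(c(codons, stop_codon), collapse = ""),
       ledger = data.frame(position = seq_len(n_codons),
                           codon = codons,
                           amino_acid = unname(genetic_code()[codons]),
                           native_rcu = nat$rcu,
                           sampled_rare = sampled_rare,
                           table_id = reg$table_id,
                           stringsAsFactors = FALSE),
       seed = seed,
       fraction_rare = fraction_rare)
}

#' Write a harmonization ledger as TSV
#'
#' Columns: position, aa, native_codon, native_rcu, chosen_codon,
#' host_rcu, rule_note.
#'
#' @param result A `harmonization_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(result, path) {
  stopifnot(inherits(result, "harmonization_result"))
  led <- result$ledger[, c("position", "amino_acid", "native_codon",
                           "native_rcu", "chosen_codon", "host_rcu",
                           "rule_note")]
  names(led)[2] <- "aa"
  write.table(led, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a %MinMax profile as TSV
#'
#' Three columns: `window_start`, `percent` and (when a null trace is
#' supplied) `null_percent`.
#'
#' @param profile A `minmax_profile`.
#' @param path Output file.
#' @param null_trace Optional [null_model_minmax()] data frame.
#' @return `path`, invisibly.
#' @export
write_minmax <- function(profile, path, null_trace = NULL) {
  stopifnot(inherits(profile, "minmax_profile"))
  out <- profile$values
  if (!is.null(null_trace)) {
    out <- merge(out, null_trace, by = "window_start")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# flatten a report section into (section, field, value) rows
flatten_section <- function(name, x) {
  vals <- unlist(x, use.names = TRUE)
  data.frame(section = name, field = names(vals),
             value = as.character(unname(vals)),
             stringsAsFactors = FALSE)
}

#' Combined machine-readable report
#'
#' Merges any subset of a [metric_report()], a [percent_minmax()]
#' profile, an [annotate_rare()] annotation and an [rbs_occlusion()]
#' verdict into one versioned report with deterministic field order.
#' Empty sections are omitted; JSON and TSV emissions carry identical
#' values.
#'
#' @param metrics Optional `metric_report`.
#' @param minmax Optional `minmax_profile`.
#' @param rare Optional `rare_codon_annotation`.
#' @param occlusion Optional [rbs_occlusion()] result.
#' @param file_json,file_tsv Optional output paths.
#' @return The report list (schema `codonharmony-report/1`), invisibly
#'   when written to file.
#' @export
workbench_report <- function(metrics = NULL, minmax = NULL, rare = NULL,
                             occlusion = NULL, file_json = NULL,
                             file_tsv = NULL) {
  rep <- list(schema = "codonharmony-report/1")
  if (!is.null(metrics)) {
    stopifnot(inherits(metrics, "metric_report"))
    rep$metrics <- list(cai = metrics$cai, nc = metrics$nc,
                        arcu = metrics$arcu,
                        gc_percent = metrics$gc_percent,
                        n_rare = metrics$n_rare,
                        n_codons = metrics$n_codons)
  }
  if (!is.null(minmax)) {
    stopifnot(inherits(minmax, "minmax_profile"))
    rep$minmax <- list(window_size = minmax$window_size,
                       table_id = minmax$table_id,
                       window_start = minmax$values$window_start,
                       percent = minmax$values$percent)
  }
  if (!is.null(rare)) {
    stopifnot(inherits(rare, "rare_codon_annotation"))
    rep$rare <- list(threshold = rare$threshold,
                     position = rare$positions$position,
                     codon = rare$positions$codon,
                     native_rcu = rare$positions$native_rcu)
  }
  if (!is.null(occlusion)) {
    rep$occlusion <- list(verdict = occlusion$verdict,
                          rbs_paired_fraction =
                            occlusion$rbs_paired_fraction)
  }
  if (!is.null(file_json)) {
    jsonlite::write_json(rep, file_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(file_tsv)) {
    rows <- do.call(rbind, lapply(names(rep)[-1], function(nm) {
      flatten_section(nm, rep[[nm]])
    }))
    if (is.null(rows)) {
      rows <- data.frame(section = character(0), field = character(0),
                         value = character(0))
    }
    write.table(rows, file_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(rep)
}
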