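# Region maps assign codon intervals of a chimeric gene to the usage
# table of the species each part is native to, so every engine can score
# "native" relative usage with the right table per segment.

#' Map codon intervals of a chimeric gene to native usage tables
#'
#' @param segments Data frame with columns `start`, `end` (1-based
#'   inclusive codon positions) and `table_id` (name into `tables`).
#'   Segments must be sorted, non-overlapping and contiguous.
#' @param tables Named list of [codon_usage_table()]s resolving every
#'   `table_id`.
#' @return Object of class `region_map`.
#' @export
#' @examples
#' \dontrun{
#' mm <- load_usage_table(fixture_table_path("mouse"))
#' bx <- load_usage_table(fixture_table_path("burkholderia"))
#' rm <- region_map(data.frame(start = c(1, 45, 125),
#'                             end = c(44, 124, 311),
#'                             table_id = c("mouse", "bxeno", "mouse")),
#'                  tables = list(mouse = mm, bxeno = bx))
#' }
region_map <- function(segments, tables) {
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "table_id") %in% names(segments)))
  segments <- segments[order(segments$start), , drop = FALSE]
  if (any(segments$end < segments$start)) {
    stop("region segment with end < start", call. = FALSE)
  }
  if (nrow(segments) > 1L) {
    gaps <- segments$start[-1L] - segments$end[-nrow(segments)]
    if (any(gaps != 1L)) {
      stop("region segments must be contiguous and non-overlapping",
           call. = FALSE)
    }
  }
  if (segments$start[1L] != 1L) {
    stop("region map must start at codon 1", call. = FALSE)
  }
  missing <- setdiff(unique(segments$table_id), names(tables))
  if (length(missing)) {
    stop(sprintf("unresolvable table_id(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (id in unique(segments$table_id)) {
    if (!inherits(tables[[id]], "codon_usage_table")) {
      stop(sprintf("tables[['%s']] is not a codon_usage_table", id),
           call. = FALSE)
    }
  }
  structure(list(segments = segments, tables = tables),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("region map: %d segment(s), codons 1-%d\n",
              nrow(x$segments), max(x$segments$end)))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

# Accept either a codon_usage_table (single region covering L codons) or
# a region_map; return per-position table ids and the table list.
resolve_regions <- function(native, n_codons) {
  if (inherits(native, "codon_usage_table")) {
    id <- native$species
    return(list(table_id = rep(id, n_codons),
                tables = setNames(list(native), id)))
  }
  if (!inherits(native, "region_map")) {
    stop("`native` must be a codon_usage_table or a region_map",
         call. = FALSE)
  }
  seg <- native$segments
  covered <- max(seg$end)
  # a map may omit a terminal stop codon (it is never scored)
  if (covered != n_codons && covered != n_codons - 1L) {
    stop(sprintf("region map covers codons 1-%d but sequence has %d codons",
                 covered, n_codons), call. = FALSE)
  }
  ids <- character(n_codons)
  for (i in seq_len(nrow(seg))) {
    ids[seg$start[i]:seg$end[i]] <- seg$table_id[i]
  }
  if (covered == n_codons - 1L) ids[n_codons] <- seg$table_id[nrow(seg)]
  list(table_id = ids, tables = native$tables)
}

# per-position native rcu for a codon vector under a table/region map;
# stop codons get NA (they are never scored)
native_rcu_by_position <- function(codons, native) {
  reg <- resolve_regions(native, length(codons))
  rcu <- rep(NA_real_, length(codons))
  for (id in unique(reg$table_id)) {
    sel <- which(reg$table_id == id)
    tab <- reg$tables[[id]]
    cod <- codons[sel]
    ok <- cod %in% sense_codons()
    rcu[sel[ok]] <- unname(tab$rcu[cod[ok]])
  }
  list(rcu = rcu, table_id = reg$table_id, tables = reg$tables)
}
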