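#' Dereplicate reads into a sequence-type table
#'
#' Collapses identical reads into unique sequence types and tabulates their
#' abundance per plot. The result is the S-by-r abundance table the whole
#' downstream analysis (clustering, network AIC, ecology) operates on:
#' one row per distinct sequence, one count column per plot.
#'
#' Rows are ordered by decreasing total abundance, ties broken
#' lexicographically by sequence, so dereplication is fully deterministic.
#'
#' @param records Tibble of reads as returned by [read_amplicon_fasta()]
#'   (columns `plot`, `sequence`; `read_id` is ignored).
#' @param min_length Reads shorter than this are dropped before
#'   dereplication. Default 1 (keep everything).
#' @param trim_to Optional length to which all reads are truncated before
#'   dereplication (e.g. the 432 bp convention for 454 nirS amplicons);
#'   reads shorter than `trim_to` are dropped. Default `NULL` (no trim).
#' @param plots Optional character vector fixing the plot column order
#'   (useful to keep empty plots); defaults to the sorted labels observed.
#' @return A `seqtype_tbl`: a tibble whose first column is `sequence` and
#'   whose remaining columns are integer per-plot read counts.
#' @examples
#' reads <- tibble::tibble(
#'   read_id = c("r1", "r2", "r3"),
#'   plot = c("P1", "P1", "P2"),
#'   sequence = c("ACGT", "ACGT", "ACGT")
#' )
#' dereplicate(reads)
#' @export
dereplicate <- function(records, min_length = 1L, trim_to = NULL,
                        plots = NULL) {
  if (nrow(records) == 0L) {
    abort("no reads to dereplicate", class = "otunet_data_error")
  }
  seqs <- records$sequence
  keep <- nchar(seqs) >= max(min_length, 1L)
  if (!is.null(trim_to)) {
    keep <- keep & nchar(seqs) >= trim_to
    seqs <- substr(seqs, 1L, trim_to)
  }
  if (!any(keep)) {
    abort("all reads removed by length filtering", class = "otunet_data_error")
  }
  df <- tibble::tibble(sequence = seqs[keep], plot = records$plot[keep])
  if (is.null(plots)) plots <- sort(unique(df$plot))
  counts <- df |>
    dplyr::count(.data$sequence, .data$plot) |>
    tidyr::pivot_wider(names_from = "plot", values_from = "n",
                       values_fill = 0L)
  for (p in setdiff(plots, names(counts))) counts[[p]] <- 0L
  counts <- counts[, c("sequence", plots)]
  tot <- rowSums(counts[, -1, drop = FALSE])
  counts <- counts[order(-tot, counts$sequence), ]
  new_seqtype_tbl(counts)
}

new_seqtype_tbl <- function(x) {
  stopifnot(names(x)[1] == "sequence")
  x[-1] <- lapply(x[-1], as.integer)
  structure(tibble::as_tibble(x), class = c("seqtype_tbl", class(tibble::tibble())))
}

#' Plot labels of a sequence-type table
#' @param x A `seqtype_tbl`.
#' @return Character vector of plot labels (column order).
#' @export
st_plots <- function(x) names(x)[-1]

#' Abundance matrix of a sequence-type table
#' @param x A `seqtype_tbl`.
#' @return Integer S-by-r matrix, rownames = sequences.
#' @export
st_abundance <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- x$sequence
  m
}

#' Write / read a sequence-type abundance table as TSV
#'
#' The dialect is a header row `sequence<TAB>plot1...plotr` followed by one
#' row per sequence type with integer counts. `read_seqtype_table()` is the
#' exact inverse of `write_seqtype_table()` on valid tables.
#'
#' @param x A `seqtype_tbl`.
#' @param path File path.
#' @return `write_seqtype_table()` returns `path` invisibly;
#'   `read_seqtype_table()` returns a `seqtype_tbl`.
#' @export
write_seqtype_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_seqtype_table
#' @export
read_seqtype_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sequence = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (names(x)[1] != "sequence") {
    abort("malformed sequence-type table: first column must be 'sequence'",
          class = "otunet_parse_error")
  }
  counts <- as.matrix(x[, -1, drop = FALSE])
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0("malformed sequence-type table at line ", bad[1, 1] + 1L,
                 ": abundances must be non-negative integers"),
          class = "otunet_parse_error")
  }
  new_seqtype_tbl(x)
}

#' Expand a sequence-type table back into individual reads
#'
#' Inverse of [dereplicate()] up to read ids: emits one row per read with
#' synthetic ids. Mainly useful for testing and simulation plumbing.
#'
#' @param x A `seqtype_tbl`.
#' @return Tibble with columns `read_id`, `plot`, `sequence`.
#' @export
expand_reads <- function(x) {
  m <- st_abundance(x)
  plots <- st_plots(x)
  rows <- which(m > 0, arr.ind = TRUE)
  out <- purrr::map_dfr(seq_len(nrow(rows)), function(k) {
    i <- rows[k, 1]; q <- rows[k, 2]
    tibble::tibble(plot = plots[q], sequence = x$sequence[i],
                   .rows = m[i, q])
  })
  out <- out[order(out$plot, out$sequence), ]
  tibble::tibble(read_id = sprintf("read%06d", seq_len(nrow(out))),
                 plot = out$plot, sequence = out$sequence)
}
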