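#' Read demultiplexed amplicon reads from FASTA
#'
#' Parses a FASTA file of amplicon reads and attaches a plot (sample) label
#' to every read, either from a two-column mapping (read id, plot) or by
#' extracting a token from the FASTA header. Reads containing characters
#' other than A/C/G/T after uppercasing (ambiguous bases such as N) are
#' dropped and counted, mirroring the usual amplicon quality filter.
#'
#' @param path Path to a FASTA file (wrapped or single-line).
#' @param mapping Optional read-to-plot mapping: either a path to a
#'   tab-separated file with columns `read_id` and `plot` (no header
#'   required), or a data frame with those two columns. When supplied it
#'   takes precedence over `header_pattern`.
#' @param header_pattern Regular expression with one capture group applied
#'   to the full FASTA header to extract the plot label. The default takes
#'   the token after the last `|`, a common 454-era convention.
#' @return A tibble with columns `read_id`, `plot`, `sequence`, one row per
#'   retained read in file order. The number of reads dropped for ambiguous
#'   bases is attached as attribute `dropped` (and reported via a message).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1|P1", "ACGT", ">r2|P2", "ACGA"), fa)
#' read_amplicon_fasta(fa)
#' @export
read_amplicon_fasta <- function(path, mapping = NULL,
                                header_pattern = "^.*\\|([^|]+)$") {
  if (!file.exists(path)) {
    abort(paste0("cannot read FASTA file: ", path), class = "otunet_io_error")
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    warn("FASTA file contains no reads")
    return(tibble::tibble(read_id = character(), plot = character(),
                          sequence = character()))
  }
  headers <- names(seqs)
  read_id <- sub("\\s.*$", "", headers)
  sequence <- unname(toupper(as.character(seqs)))

  if (!is.null(mapping)) {
    if (is.character(mapping) && length(mapping) == 1L) {
      mapping <- read_mapping(mapping)
    }
    stopifnot(all(c("read_id", "plot") %in% names(mapping)))
    idx <- match(read_id, mapping$read_id)
    if (anyNA(idx)) {
      missing <- read_id[which(is.na(idx))[1]]
      abort(paste0("read has no plot mapping: ", missing),
            class = "otunet_mapping_error")
    }
    plot <- as.character(mapping$plot)[idx]
  } else {
    hit <- grepl(header_pattern, headers)
    if (!all(hit)) {
      abort(paste0("read header does not match header_pattern: ",
                   headers[which(!hit)[1]]),
            class = "otunet_mapping_error")
    }
    plot <- sub(header_pattern, "\\1", headers)
  }

  clean <- grepl("^[ACGT]+$", sequence)
  dropped <- sum(!clean)
  if (dropped > 0L) {
    inform(paste0("dropped ", dropped,
                  " read(s) containing ambiguous (non-ACGT) bases"))
  }
  out <- tibble::tibble(read_id = read_id, plot = plot,
                        sequence = sequence)[clean, ]
  attr(out, "dropped") <- dropped
  out
}

#' Read a read-to-plot mapping file
#'
#' @param path Tab-separated file with two columns: read id, plot label.
#'   A header line `read_id<TAB>plot` is accepted and skipped.
#' @return Tibble with columns `read_id`, `plot`.
#' @export
read_mapping <- function(path) {
  x <- readr::read_tsv(path, col_names = c("read_id", "plot"),
                       col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (nrow(x) > 0 && x$read_id[1] == "read_id") x <- x[-1, ]
  x
}

#' Write a read-to-plot mapping file
#'
#' @param records Data frame with columns `read_id` and `plot`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(records, path) {
  readr::write_tsv(records[, c("read_id", "plot")], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Write amplicon reads to FASTA
#'
#' Headers are written as `read_id|plot` so the default header rule of
#' [read_amplicon_fasta()] round-trips the plot labels.
#'
#' @param records Data frame with columns `read_id`, `plot`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amplicon_fasta <- function(records, path) {
  seqs <- Biostrings::BStringSet(records$sequence)
  names(seqs) <- paste0(records$read_id, "|", records$plot)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
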