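#' Global-alignment identity between two DNA sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1 and a
#' linear gap cost of -2 per gap column. Identity is the number of
#' matching aligned columns divided by the full alignment length, gap
#' columns included. On equal score the traceback prefers a
#' match/mismatch column over a gap, and sequences are aligned in
#' canonical (lexicographic) order, so the result is deterministic and
#' exactly symmetric.
#'
#' @param a,b Non-empty A/C/G/T strings.
#' @return Identity fraction in \[0, 1\].
#' @examples
#' pairwise_identity("ACGT", "ACGA") # 0.75
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (nchar(a) == 0 || nchar(b) == 0) {
    abort("sequences must be non-empty", class = "otunet_data_error")
  }
  if (a == b) return(1.0)
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  nw_identity_cpp(a, b)$identity
}

#' Alignment details for two sequences
#'
#' Like [pairwise_identity()] but returns the optimal score, match count
#' and alignment length as well. Mostly useful for auditing the scoring
#' scheme.
#'
#' @inheritParams pairwise_identity
#' @return List with elements `score`, `matches`, `length`, `identity`.
#' @export
pairwise_alignment <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) {
    abort("sequences must be non-empty", class = "otunet_data_error")
  }
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  nw_identity_cpp(a, b)
}

#' Pairwise alignment distances for a sequence-type table
#'
#' Computes d = 1 - identity for every pair of sequence types, using the
#' alignment of [pairwise_identity()]. All O(S^2) pairs are aligned
#' exactly; this is intended for dereplicated tables at desk scale, not
#' raw read sets.
#'
#' @param table A `seqtype_tbl` (or a character vector of sequences).
#' @return A base [stats::dist] object over the sequence types, in table
#'   row order.
#' @export
compute_distances <- function(table) {
  seqs <- if (is.character(table)) table else table$sequence
  n <- length(seqs)
  stopifnot(n >= 1)
  d <- nw_distances_cpp(seqs)
  attributes(d) <- list(Size = n, Diag = FALSE, Upper = FALSE,
                        method = "nw", class = "dist",
                        Labels = as.character(seq_len(n)))
  d
}

#' Write / read a condensed distance matrix as TSV
#'
#' One header line `n<TAB><size>` followed by one distance per line in
#' [stats::dist] condensed order.
#'
#' @param d A `dist` object.
#' @param path File path.
#' @export
write_distances <- function(d, path) {
  n <- attr(d, "Size")
  writeLines(c(paste0("n\t", n), format(as.numeric(d), digits = 17)), path)
  invisible(path)
}

#' @rdname write_distances
#' @export
read_distances <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) != 2 || hdr[1] != "n") {
    abort("malformed distance file: expected 'n<TAB><size>' header",
          class = "otunet_parse_error")
  }
  n <- as.integer(hdr[2])
  d <- as.numeric(lines[-1])
  stopifnot(length(d) == n * (n - 1) / 2)
  attributes(d) <- list(Size = n, Diag = FALSE, Upper = FALSE,
                        method = "nw", class = "dist",
                        Labels = as.character(seq_len(n)))
  d
}

linkage_tree <- function(dm) {
  n <- attr(dm, "Size")
  if (n < 2) return(NULL)
  hclust(dm, method = "average")
}

#' Cluster sequence types into OTUs at one similarity threshold
#'
#' Average-linkage hierarchical clustering of the alignment distances,
#' with the tree cut at distance (100 - similarity)/100; two sequence
#' types share an OTU iff their cluster's merge height is at or below the
#' cut (inclusive). OTU ids are assigned in order of decreasing OTU total
#' abundance (ties: lexicographically smallest member sequence), and each
#' OTU's representative is its most abundant member (ties again broken by
#' sequence), so partitions are reproducible without seeds.
#'
#' @param dm A `dist` from [compute_distances()].
#' @param similarity_pct Similarity threshold in (0, 100].
#' @param table The `seqtype_tbl` the distances were computed from
#'   (supplies abundances for id/representative ordering). Optional: when
#'   omitted every sequence type counts 1 and ordering falls back to the
#'   original row order.
#' @param tree Precomputed average-linkage `hclust` for `dm` (used by
#'   [cluster_scan()] so all thresholds cut the same tree).
#' @return A `partition` object: list with `threshold_pct`, `assignment`
#'   (integer OTU id per sequence type, 1-based), `k`, and
#'   `representatives` (sequence-type index per OTU).
#' @export
cluster_at <- function(dm, similarity_pct, table = NULL, tree = NULL) {
  if (similarity_pct <= 0 || similarity_pct > 100) {
    abort("similarity_pct must be in (0, 100]", class = "otunet_data_error")
  }
  n <- attr(dm, "Size")
  cut <- (100 - similarity_pct) / 100
  if (n == 1) {
    raw <- 1L
  } else {
    if (is.null(tree)) tree <- linkage_tree(dm)
    # cutree(h = cut) keeps together every merge with height <= cut
    raw <- unname(cutree(tree, h = cut))
  }
  relabel_partition(raw, similarity_pct, table)
}

relabel_partition <- function(raw, similarity_pct, table = NULL) {
  n <- length(raw)
  if (!is.null(table)) {
    tot <- rowSums(st_abundance(table))
    seqs <- table$sequence
  } else {
    tot <- rep(1, n)
    seqs <- sprintf("%09d", seq_len(n))
  }
  ids <- sort(unique(raw))
  otu_tot <- vapply(ids, function(g) sum(tot[raw == g]), numeric(1))
  otu_min_seq <- vapply(ids, function(g) min(seqs[raw == g]), character(1))
  ord <- order(-otu_tot, otu_min_seq)
  new_id <- integer(max(ids)); new_id[ids[ord]] <- seq_along(ids)
  assignment <- new_id[raw]
  reps <- vapply(seq_along(ids), function(g) {
    members <- which(assignment == g)
    members[order(-tot[members], seqs[members])][1]
  }, integer(1))
  structure(list(threshold_pct = similarity_pct,
                 assignment = assignment,
                 k = length(ids),
                 representatives = reps),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("OTU partition at ", x$threshold_pct, "% similarity: ",
      length(x$assignment), " sequence types in ", x$k, " OTUs\n", sep = "")
  invisible(x)
}

#' @export
tidy.partition <- function(x, ...) {
  tibble::tibble(sequence_index = seq_along(x$assignment),
                 otu_id = x$assignment,
                 threshold_pct = x$threshold_pct)
}

#' Scan a grid of similarity thresholds
#'
#' Cuts one average-linkage tree at every threshold of the grid (default
#' the integer grid 74-99%), guaranteeing that partitions are nested: the
#' partition at a lower similarity is a coarsening of the one at any
#' higher similarity, and the OTU count k is non-decreasing in similarity.
#'
#' @inheritParams cluster_at
#' @param grid Strictly increasing integer similarity levels; default 74:99.
#' @return A `cluster_scan`: list of `partition` objects, one per level.
#' @export
cluster_scan <- function(dm, grid = 74:99, table = NULL) {
  if (length(grid) == 0 || any(diff(grid) <= 0)) {
    abort("grid must be non-empty and strictly increasing",
          class = "otunet_data_error")
  }
  tree <- linkage_tree(dm)
  parts <- purrr::map(grid, function(s) cluster_at(dm, s, table, tree = tree))
  structure(parts, class = "cluster_scan", grid = grid)
}

#' @export
print.cluster_scan <- function(x, ...) {
  k <- vapply(x, function(p) p$k, integer(1))
  cat("Cluster scan over ", length(x), " thresholds (",
      min(attr(x, "grid")), "-", max(attr(x, "grid")), "%), k = ",
      min(k), "..", max(k), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.cluster_scan <- function(x, ...) {
  purrr::map_dfr(x, tidy)
}

#' Write a partition (or scan) as TSV
#'
#' Columns `sequence_index`, `otu_id`, `threshold_pct`.
#'
#' @param x A `partition` or `cluster_scan`.
#' @param path File path.
#' @export
write_partition <- function(x, path) {
  readr::write_tsv(tidy(x), path, progress = FALSE)
  invisible(path)
}
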