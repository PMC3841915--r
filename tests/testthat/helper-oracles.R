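# Independent oracles used to freeze and verify expected values.
# Everything here is deliberately naive (enumeration, direct summation,
# hand-rolled pmfs) and shares no code with the package internals.

# --- exhaustive global alignment oracle (short sequences only) -----------
# Enumerates every global alignment of a and b, scores them with
# match +1 / mismatch -1 / gap -2 per gap column, and returns the maximal
# score together with the set of identities (matches / columns) attained
# by maximal-score alignments.
oracle_align <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf
  best$identities <- numeric(0)
  recurse <- function(i, j, score, matches, len) {
    if (i > length(av) && j > length(bv)) {
      if (score > best$score) {
        best$score <- score
        best$identities <- matches / len
      } else if (score == best$score) {
        best$identities <- union(best$identities, matches / len)
      }
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      hit <- av[i] == bv[j]
      recurse(i + 1, j + 1, score + if (hit) 1 else -1,
              matches + hit, len + 1)
    }
    if (i <= length(av)) recurse(i + 1, j, score - 2, matches, len + 1)
    if (j <= length(bv)) recurse(i, j + 1, score - 2, matches, len + 1)
  }
  recurse(1, 1, 0, 0, 0)
  list(score = best$score, identities = sort(best$identities))
}

# --- hand-rolled log-pmfs -------------------------------------------------
oracle_log_pois <- function(x, lambda) {
  if (lambda == 0) return(if (x == 0) 0 else -Inf)
  x * log(lambda) - lambda - lfactorial(x)
}

oracle_log_binom <- function(x, size, p) {
  if (size == 0) return(if (x == 0) 0 else -Inf)
  if (p == 1) return(if (x == size) 0 else -Inf)   # degenerate at S_i = 1
  lchoose(size, x) + x * log(p) + (size - x) * log(1 - p)
}

# --- naive direct-summation reimplementation of the network scores -------
# assignment: integer OTU id per sequence-type row of `abund` (S x r).
oracle_network_scores <- function(abund, assignment,
                                  model = "poisson",
                                  verbatim_sign = FALSE) {
  otus <- sort(unique(assignment))
  k <- length(otus)
  r <- ncol(abund)
  S <- nrow(abund)
  ll_bin <- 0
  ll_ab <- 0
  ll_bin_mat <- matrix(0, k, r)
  ll_ab_mat <- matrix(0, k, r)
  for (ii in seq_along(otus)) {
    members <- which(assignment == otus[ii])
    S_i <- length(members)
    for (q in seq_len(r)) {
      L <- sum(abund[members, q] > 0)
      p <- L / S_i
      term1 <- if (L == 0) 0 else L * log(p)
      miss <- if (verbatim_sign) L - S_i else S_i - L
      term2 <- if (miss == 0) 0 else miss * log(1 - p)
      ll_bin_mat[ii, q] <- term1 + term2
      ll_bin <- ll_bin + term1 + term2
      a_dot <- sum(abund[members, q])
      contrib <- 0
      for (j in members) {
        contrib <- contrib + if (model == "poisson") {
          oracle_log_pois(abund[j, q], a_dot / S_i)
        } else {
          oracle_log_binom(abund[j, q], a_dot, 1 / S_i)
        }
      }
      ll_ab_mat[ii, q] <- contrib
      ll_ab <- ll_ab + contrib
    }
  }
  list(k = k, r = r, S = S,
       ll_binary = ll_bin, ll_abund = ll_ab,
       ll_binary_mat = ll_bin_mat, ll_abund_mat = ll_ab_mat,
       aic_binary = 2 * k * r + 2 * S - 2 * ll_bin,
       aic_weighted = 4 * k * r + 2 * S - 2 * (ll_bin + ll_ab))
}

# --- random fixtures ------------------------------------------------------
random_network_case <- function() {
  k <- sample(1:10, 1)
  r <- sample(1:8, 1)
  S <- sample(k:40, 1)
  assignment <- c(seq_len(k), sample(seq_len(k), S - k, replace = TRUE))
  abund <- matrix(rpois(S * r, 3), S, r)
  abund[matrix(runif(S * r) < 0.4, S, r)] <- 0L
  # every sequence type must have total abundance >= 1
  empty <- rowSums(abund) == 0
  abund[cbind(which(empty), sample(seq_len(r), sum(empty), replace = TRUE))] <- 1L
  list(abund = abund, assignment = assignment)
}

make_table <- function(sequences, abund, plots = NULL) {
  if (is.null(plots)) plots <- sprintf("P%d", seq_len(ncol(abund)))
  df <- tibble::tibble(sequence = sequences)
  for (q in seq_along(plots)) df[[plots[q]]] <- as.integer(abund[, q])
  otunet:::new_seqtype_tbl(df)
}

as_partition <- function(assignment, threshold = 88) {
  otunet:::relabel_partition(as.integer(assignment), threshold)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

net_fixture <- function(abund, assignment) {
  tab <- make_table(sprintf("%04d", seq_len(nrow(abund))), abund)
  build_network(tab, as_partition(assignment))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
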