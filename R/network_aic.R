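#' Build the bipartite OTU-by-plot network for a partition
#'
#' The object scored by the network likelihoods: S sequence types grouped
#' into k OTUs connected to r plots. For OTU i and plot q, `L[i, q]` is
#' the number of member sequence types observed (abundance > 0) in plot q
#' and `a_dot[i, q]` the summed abundance of OTU i in plot q.
#'
#' @param table A `seqtype_tbl` with S rows.
#' @param partition A `partition` over the same S sequence types.
#' @return A `bipartite_network`: list with `k`, `r`, `S`, `S_i` (length-k
#'   member counts), `L` (k x r link counts), `a_dot` (k x r summed
#'   abundances), `members` (list of member row indices per OTU),
#'   `abundance` (the S x r member abundance matrix), `plots`,
#'   `threshold_pct` and `L_total`.
#' @export
build_network <- function(table, partition) {
  m <- st_abundance(table)
  S <- nrow(m)
  if (length(partition$assignment) != S) {
    abort("partition and table disagree on the number of sequence types",
          class = "otunet_data_error")
  }
  k <- partition$k
  members <- split(seq_len(S), partition$assignment)
  names(members) <- NULL
  pres <- m > 0
  L <- t(vapply(members, function(js) colSums(pres[js, , drop = FALSE]),
                numeric(ncol(m))))
  a_dot <- t(vapply(members, function(js) colSums(m[js, , drop = FALSE]),
                    numeric(ncol(m))))
  if (ncol(m) == 1L) { L <- matrix(L, ncol = 1); a_dot <- matrix(a_dot, ncol = 1) }
  dimnames(L) <- NULL
  dimnames(a_dot) <- NULL
  structure(list(k = k, r = ncol(m), S = S,
                 S_i = lengths(members),
                 L = L, a_dot = a_dot,
                 members = members,
                 abundance = m,
                 plots = st_plots(table),
                 threshold_pct = partition$threshold_pct,
                 L_total = sum(L)),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat("Bipartite OTU-plot network: ", x$S, " sequence types in ", x$k,
      " OTUs x ", x$r, " plots, ", x$L_total, " links\n", sep = "")
  invisible(x)
}

#' @export
tidy.bipartite_network <- function(x, ...) {
  tidyr::expand_grid(otu_id = seq_len(x$k), plot = x$plots) |>
    dplyr::mutate(S_i = x$S_i[.data$otu_id],
                  links = as.vector(t(x$L)),
                  abundance = as.vector(t(x$a_dot)))
}

#' Link probability of an OTU-plot association
#'
#' The probability of drawing a member sequence type of OTU `i` at random
#' and finding it present in plot `q`: `L[i, q] / S_i`.
#'
#' @param net A `bipartite_network`.
#' @param i OTU index.
#' @param q Plot index.
#' @return Probability in \[0, 1\].
#' @export
link_probability <- function(net, i, q) {
  net$L[i, q] / net$S_i[i]
}

# elementwise binary occurrence log-likelihood matrix (k x r)
binary_ll_matrix <- function(net, verbatim_sign = FALSE) {
  p <- net$L / net$S_i
  miss <- if (verbatim_sign) net$L - net$S_i else net$S_i - net$L
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  xlogy(net$L, p) + xlogy(miss, 1 - p)
}

#' Binary occurrence log-likelihood of one OTU-plot association
#'
#' With p = L/S_i the default (corrected-sign) contribution is
#' `L*log(p) + (S_i - L)*log(1 - p)`, using the convention 0*log(0) = 0;
#' it is 0 when every member or no member of the OTU occurs in the plot,
#' and negative otherwise. `verbatim_sign = TRUE` instead uses the
#' exponent `(L - S_i)` on the second term, reproducing a printed variant
#' of the formula whose sign is widely regarded as a typo (it makes the
#' term positive); see the package vignette.
#'
#' @inheritParams link_probability
#' @param verbatim_sign Use the literal `(L - S_i)` exponent. Default FALSE.
#' @return Log-likelihood contribution (<= 0 in the default mode).
#' @export
binary_ll <- function(net, i, q, verbatim_sign = FALSE) {
  binary_ll_matrix(net, verbatim_sign)[i, q]
}

#' Binary network AIC
#'
#' `2*k*r + 2*S - 2 * sum(binary_ll)` over all OTU-plot associations.
#'
#' @inheritParams binary_ll
#' @return AIC value.
#' @export
binary_aic <- function(net, verbatim_sign = FALSE) {
  2 * net$k * net$r + 2 * net$S - 2 * sum(binary_ll_matrix(net, verbatim_sign))
}

# per-association abundance log-likelihood (k x r matrix)
abundance_ll_matrix <- function(net, model = c("poisson", "binomial")) {
  model <- match.arg(model)
  out <- matrix(0, net$k, net$r)
  for (i in seq_len(net$k)) {
    rows <- net$abundance[net$members[[i]], , drop = FALSE]
    S_i <- net$S_i[i]
    if (model == "poisson") {
      lam <- rep(net$a_dot[i, ] / S_i, each = S_i)
      ll <- dpois(as.vector(rows), lam, log = TRUE)
      # lambda = 0 cells: degenerate Poisson at 0 observing 0 contributes 0
      ll[lam == 0 & as.vector(rows) == 0] <- 0
    } else {
      size <- rep(net$a_dot[i, ], each = S_i)
      ll <- dbinom(as.vector(rows), size, 1 / S_i, log = TRUE)
      ll[size == 0 & as.vector(rows) == 0] <- 0
    }
    out[i, ] <- colSums(matrix(ll, nrow = S_i))
  }
  out
}

#' Abundance-weighted log-likelihood of one OTU-plot association
#'
#' Sums, over the S_i member sequence types j of OTU i (members absent
#' from the plot included), the log-pmf of the member's abundance under a
#' within-OTU exchangeability model: Poisson with mean `a_dot/S_i`, or
#' Binomial with `size = a_dot` and `p = 1/S_i`. Degenerate cases (OTU
#' absent from the plot, or a single-member OTU under the Binomial)
#' contribute 0.
#'
#' @inheritParams link_probability
#' @param model `"poisson"` (default) or `"binomial"`.
#' @return Log-likelihood contribution (<= 0).
#' @export
abundance_ll <- function(net, i, q, model = c("poisson", "binomial")) {
  abundance_ll_matrix(net, model)[i, q]
}

#' Abundance-weighted network AIC
#'
#' `4*k*r + 2*S - 2 * sum(binary_ll + abundance_ll)`: the binary model
#' plus the abundance model, with the extra `2*k*r` parameters of the
#' per-association abundance means.
#'
#' @inheritParams abundance_ll
#' @inheritParams binary_ll
#' @return AIC value.
#' @export
weighted_aic <- function(net, model = c("poisson", "binomial"),
                         verbatim_sign = FALSE) {
  4 * net$k * net$r + 2 * net$S -
    2 * (sum(binary_ll_matrix(net, verbatim_sign)) +
           sum(abundance_ll_matrix(net, model)))
}

#' Score a threshold scan by network AIC
#'
#' Builds the bipartite network for every partition in the scan and
#' computes the binary and abundance-weighted AIC. The optimal threshold
#' is the argmin of the selected AIC column; exact ties go to the lower
#' similarity (the coarser, more parsimonious clustering).
#'
#' @param table A `seqtype_tbl`.
#' @param scan A `cluster_scan` over the same table.
#' @param model Abundance model, `"poisson"` (default) or `"binomial"`.
#' @param weighted Select on the abundance-weighted AIC (default TRUE) or
#'   the binary AIC.
#' @param verbatim_sign Passed to the binary likelihood.
#' @return An `aic_curve`: a tibble with one row per threshold (columns
#'   `threshold_pct`, `k`, `ll_binary`, `ll_abund`, `aic_binary`,
#'   `aic_weighted`, `model`) carrying attributes `optimal_threshold` and
#'   `selection` (the column minimised).
#' @export
aic_curve <- function(table, scan, model = c("poisson", "binomial"),
                      weighted = TRUE, verbatim_sign = FALSE) {
  model <- match.arg(model)
  if (length(scan) == 0) abort("empty scan", class = "otunet_data_error")
  rows <- purrr::map_dfr(scan, function(part) {
    net <- build_network(table, part)
    llb <- sum(binary_ll_matrix(net, verbatim_sign))
    lla <- sum(abundance_ll_matrix(net, model))
    tibble::tibble(threshold_pct = part$threshold_pct, k = part$k,
                   ll_binary = llb, ll_abund = lla,
                   aic_binary = 2 * net$k * net$r + 2 * net$S - 2 * llb,
                   aic_weighted = 4 * net$k * net$r + 2 * net$S -
                     2 * (llb + lla),
                   model = model)
  })
  selection <- if (weighted) "aic_weighted" else "aic_binary"
  opt <- rows$threshold_pct[which.min(rows[[selection]])]
  structure(rows, class = c("aic_curve", class(rows)),
            optimal_threshold = opt, selection = selection)
}

#' Optimal threshold of an AIC curve
#'
#' @param curve An `aic_curve`.
#' @return The AIC-minimising similarity threshold (ties resolved toward
#'   the lower threshold).
#' @export
select_optimal <- function(curve) {
  if (nrow(curve) == 0) abort("empty AIC curve", class = "otunet_data_error")
  attr(curve, "optimal_threshold")
}

#' @export
print.aic_curve <- function(x, ...) {
  cat("AIC curve over ", nrow(x), " thresholds; optimum ",
      attr(x, "optimal_threshold"), "% (", attr(x, "selection"), ", ",
      x$model[1], " abundance model)\n", sep = "")
  NextMethod()
}

#' @export
glance.aic_curve <- function(x, ...) {
  i <- which.min(x[[attr(x, "selection")]])
  tibble::tibble(optimal_threshold = attr(x, "optimal_threshold"),
                 k = x$k[i],
                 aic_min = x[[attr(x, "selection")]][i],
                 selection = attr(x, "selection"),
                 model = x$model[1])
}

#' @export
tidy.aic_curve <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Plot an AIC curve
#'
#' AIC against similarity threshold with the selected optimum marked.
#'
#' @param object An `aic_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aic_curve <- function(object, ...) {
  sel <- attr(object, "selection")
  ggplot2::ggplot(object, ggplot2::aes(.data$threshold_pct, .data[[sel]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "optimal_threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = "similarity threshold (%)", y = "AIC",
                  title = paste0("Optimal clustering at ",
                                 attr(object, "optimal_threshold"),
                                 "% similarity")) +
    ggplot2::theme_minimal()
}

#' Write an AIC curve as TSV
#'
#' @param x An `aic_curve`.
#' @param path File path.
#' @export
write_aic_curve <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}
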