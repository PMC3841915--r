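#' End-to-end threshold selection and ecology pipeline
#'
#' Convenience wrapper chaining the whole analysis: dereplicate reads,
#' compute pairwise alignment distances, scan the similarity grid, score
#' every clustering with the bipartite network AIC, select the optimal
#' threshold, and compute the ecology summaries on the selected network.
#'
#' @param records Read tibble from [read_amplicon_fasta()] or
#'   [simulate_community()].
#' @param grid Similarity grid, default 74:99.
#' @param model Abundance model (`"poisson"` or `"binomial"`).
#' @param weighted Select on the weighted AIC (default) or binary.
#' @param verbatim_sign Use the literal printed sign of the binary
#'   likelihood's second term (see [binary_ll()]).
#' @param generalist_min Occupancy cutoff for generalists; default 6 (or
#'   a fraction of r, see [classify_otus()]).
#' @param cooccurrence_mode `"jaccard"` or `"min"`.
#' @param doses Optional per-plot covariate for the specialist gradient,
#'   aligned with the sorted plot labels.
#' @param min_length,trim_to Passed to [dereplicate()].
#' @return List with components `table`, `scan`, `curve`,
#'   `optimal_threshold`, `partition`, `network`, `profiles`,
#'   `summaries`, `cooccurrence`, `dendrogram`, and (when `doses` is
#'   given) `gradient`.
#' @export
otu_pipeline <- function(records, grid = 74:99,
                         model = c("poisson", "binomial"),
                         weighted = TRUE, verbatim_sign = FALSE,
                         generalist_min = 6,
                         cooccurrence_mode = c("jaccard", "min"),
                         doses = NULL, min_length = 1L, trim_to = NULL) {
  model <- match.arg(model)
  cooccurrence_mode <- match.arg(cooccurrence_mode)
  tab <- dereplicate(records, min_length = min_length, trim_to = trim_to)
  dm <- compute_distances(tab)
  if (nrow(tab) == 1) {
    warn("single sequence type: threshold selection is degenerate")
  }
  scan <- cluster_scan(dm, grid, tab)
  curve <- aic_curve(tab, scan, model = model, weighted = weighted,
                     verbatim_sign = verbatim_sign)
  opt <- select_optimal(curve)
  part <- scan[[match(opt, grid)]]
  net <- build_network(tab, part)
  profiles <- classify_otus(net, generalist_min = generalist_min)
  summaries <- plot_summaries(net, profiles)
  cm <- cooccurrence(net, mode = cooccurrence_mode)
  hc <- if (net$r >= 2) cluster_plots(cm) else NULL
  out <- list(table = tab, scan = scan, curve = curve,
              optimal_threshold = opt, partition = part, network = net,
              profiles = profiles, summaries = summaries,
              cooccurrence = cm, dendrogram = hc)
  if (!is.null(doses)) {
    out$gradient <- specialist_gradient(summaries, doses)
  }
  out
}
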