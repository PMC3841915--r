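#' Classify OTUs as generalists, specialists or intermediates
#'
#' Occupancy-based classification on the optimal OTU-by-plot network:
#' specialists (endemics) occur in exactly one plot, generalists in at
#' least `generalist_min` plots (the 8-plot salt-marsh convention is at
#' least 6 of 8), everything else is intermediate. A singleton is an OTU
#' represented by a single read in a single plot.
#'
#' @param net A `bipartite_network`.
#' @param generalist_min Minimum occupancy for a generalist; default 6.
#'   A value in (0, 1) is interpreted as a fraction of the plot count
#'   (e.g. 0.75 means at least 75% of plots).
#' @return Tibble with one row per OTU: `otu_id`, `occupancy`,
#'   `total_abundance`, `class` (factor: generalist / intermediate /
#'   specialist), `is_singleton`.
#' @export
classify_otus <- function(net, generalist_min = 6) {
  if (generalist_min > 0 && generalist_min < 1) {
    generalist_min <- ceiling(generalist_min * net$r)
  }
  if (generalist_min < 1 || generalist_min > net$r) {
    abort("generalist_min must be in [1, r]", class = "otunet_data_error")
  }
  occupancy <- rowSums(net$a_dot > 0)
  total <- rowSums(net$a_dot)
  class <- dplyr::case_when(
    occupancy == 1 ~ "specialist",
    occupancy >= generalist_min ~ "generalist",
    .default = "intermediate"
  )
  tibble::tibble(
    otu_id = seq_len(net$k),
    occupancy = as.integer(occupancy),
    total_abundance = as.integer(total),
    class = factor(class, levels = c("generalist", "intermediate",
                                     "specialist")),
    is_singleton = occupancy == 1 & total == 1
  )
}

#' Per-plot community summaries
#'
#' For each plot: total retained sequences, number of distinct OTUs,
#' plot-endemic OTUs (specialists occurring there), singletons, and the
#' sequence counts attributable to generalist and to endemic OTUs.
#'
#' @param net A `bipartite_network`.
#' @param profiles OTU classification from [classify_otus()] on the same
#'   network.
#' @return Tibble with one row per plot: `plot`, `total_sequences`,
#'   `unique_otus`, `endemic_otus`, `singletons`, `generalist_sequences`,
#'   `endemic_sequences`.
#' @export
plot_summaries <- function(net, profiles) {
  stopifnot(nrow(profiles) == net$k)
  pres <- net$a_dot > 0
  gen <- profiles$class == "generalist"
  spec <- profiles$class == "specialist"
  tibble::tibble(
    plot = net$plots,
    total_sequences = as.integer(colSums(net$a_dot)),
    unique_otus = as.integer(colSums(pres)),
    endemic_otus = as.integer(colSums(pres[spec, , drop = FALSE])),
    singletons = as.integer(colSums(pres[profiles$is_singleton, ,
                                         drop = FALSE])),
    generalist_sequences = as.integer(colSums(net$a_dot[gen, ,
                                                        drop = FALSE])),
    endemic_sequences = as.integer(colSums(net$a_dot[spec, ,
                                                     drop = FALSE]))
  )
}

#' Co-occurrence matrix between plots
#'
#' The fraction of OTUs shared between every pair of plots. The default
#' denominator is the union of the two plots' OTU sets (Jaccard); the
#' `"min"` mode divides instead by the smaller set, so nested communities
#' score 1.
#'
#' @param net A `bipartite_network`.
#' @param mode `"jaccard"` (default) or `"min"`.
#' @return A `cooccurrence` object: an r x r symmetric numeric matrix of
#'   fractions in \[0, 1\] with plot labels as dimnames. Plots containing
#'   no OTUs get 0 rows/columns (with a warning), including the diagonal.
#' @export
cooccurrence <- function(net, mode = c("jaccard", "min")) {
  mode <- match.arg(mode)
  pres <- net$a_dot > 0
  sizes <- colSums(pres)
  if (any(sizes == 0)) {
    warn(paste0("plot(s) with no OTUs: ",
                paste(net$plots[sizes == 0], collapse = ", ")))
  }
  shared <- crossprod(pres)
  denom <- if (mode == "jaccard") outer(sizes, sizes, `+`) - shared
           else outer(sizes, sizes, pmin)
  cm <- ifelse(denom > 0, shared / denom, 0)
  dimnames(cm) <- list(net$plots, net$plots)
  structure(cm, class = c("cooccurrence", "matrix"), mode = mode)
}

#' Complete-linkage clustering of plots by co-occurrence
#'
#' Hierarchical clustering of the plots on distance 1 - co-occurrence,
#' with complete linkage (cluster distance = maximum pairwise distance).
#' Merge order is made deterministic by the clustering of the distance
#' matrix in plot order; exact ties resolve to the smallest plot index.
#'
#' @param cm A `cooccurrence` matrix.
#' @return An [stats::hclust] object over the plots.
#' @export
cluster_plots <- function(cm) {
  if (nrow(cm) < 2) {
    abort("need at least 2 plots to cluster", class = "otunet_data_error")
  }
  hclust(as.dist(1 - unclass(cm)), method = "complete")
}

#' Export a plot dendrogram as Newick text
#'
#' @param hc An `hclust` from [cluster_plots()].
#' @param path File path.
#' @export
write_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Specialist/generalist proportion along a dose gradient
#'
#' Relates a per-plot numeric covariate (e.g. nitrogen fertilisation
#' dose) to the proportion of each plot's sequences belonging to
#' generalist and to plot-endemic OTUs.
#'
#' @param summaries Output of [plot_summaries()].
#' @param doses Numeric covariate, one value per plot, aligned with
#'   `summaries$plot`.
#' @return Tibble sorted by dose: `plot`, `dose`,
#'   `proportion_generalist_sequences`, `proportion_specialist_sequences`.
#' @export
specialist_gradient <- function(summaries, doses) {
  stopifnot(length(doses) == nrow(summaries))
  summaries |>
    dplyr::mutate(dose = doses,
                  proportion_generalist_sequences =
                    .data$generalist_sequences / .data$total_sequences,
                  proportion_specialist_sequences =
                    .data$endemic_sequences / .data$total_sequences) |>
    dplyr::select("plot", "dose", "proportion_generalist_sequences",
                  "proportion_specialist_sequences") |>
    dplyr::arrange(.data$dose, .data$plot)
}

#' Export the bipartite OTU-plot network
#'
#' Writes the OTU-plot graph with edge weight equal to the summed OTU
#' abundance in the plot and OTU nodes attributed with their occupancy
#' class. Formats: a weighted edge-list TSV (`otu`, `plot`, `weight`) or
#' GML (via igraph). Only associations with positive abundance become
#' edges; layout/rendering is left to the consumer.
#'
#' @param net A `bipartite_network`.
#' @param profiles Classification from [classify_otus()].
#' @param path Output path.
#' @param format `"edgelist"` (default) or `"gml"`.
#' @export
export_network <- function(net, profiles, path,
                           format = c("edgelist", "gml")) {
  format <- match.arg(format)
  edges <- tidy(net) |>
    dplyr::filter(.data$abundance > 0) |>
    dplyr::transmute(otu = paste0("OTU", .data$otu_id), plot = .data$plot,
                     weight = .data$abundance)
  if (format == "edgelist") {
    readr::write_tsv(edges, path, progress = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      edges,
      directed = FALSE,
      vertices = data.frame(
        name = c(paste0("OTU", profiles$otu_id), net$plots),
        type = c(rep("otu", net$k), rep("plot", net$r)),
        class = c(as.character(profiles$class), rep("", net$r))
      )
    )
    igraph::write_graph(g, path, format = "gml")
  }
  invisible(path)
}

#' Read a network edge list written by [export_network()]
#'
#' @param path Edge-list TSV path.
#' @return Tibble with columns `otu`, `plot`, `weight`.
#' @export
read_network_edgelist <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    otu = readr::col_character(), plot = readr::col_character(),
    weight = readr::col_double()), progress = FALSE)
}

#' Heatmap of plot co-occurrence
#'
#' @param cm A `cooccurrence` matrix.
#' @return A ggplot tile heatmap.
#' @export
plot_cooccurrence <- function(cm) {
  df <- tibble::as_tibble(as.table(unclass(cm)), .name_repair = "minimal")
  names(df) <- c("plot1", "plot2", "fraction")
  ggplot2::ggplot(df, ggplot2::aes(.data$plot1, .data$plot2,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "co-occurrence") +
    ggplot2::theme_minimal()
}
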