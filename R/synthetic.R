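#' Configuration for a synthetic amplicon community
#'
#' Describes a planted-OTU community emulating a replicated fertilisation
#' experiment: `k_true` core OTUs whose member sequences diverge little
#' within an OTU and strongly between OTUs, distributed over `r` plots
#' with Poisson read counts, plus plot-endemic (specialist) OTUs whose
#' expected number scales with a per-plot dose covariate. Defaults mirror
#' an 8-plot design with duplicated treatments at nitrogen doses 0, 0.85,
#' 2.52 and 7.56 g N m^-2 wk^-1 and 432 bp amplicons.
#'
#' @param seed Integer RNG seed; the whole community is a deterministic
#'   function of the configuration including the seed.
#' @param r Number of plots. Must equal `length(doses)`.
#' @param k_true Number of planted core OTUs.
#' @param ancestor_length Length of the ancestral sequences (bases).
#' @param members_per_otu Integer range (min, max) of member sequence
#'   types per core OTU.
#' @param within_divergence Maximum substitutions/site between two
#'   members of one OTU (each member is mutated from its ancestor by at
#'   most half this).
#' @param between_divergence Minimum substitutions/site between any two
#'   OTU ancestors (enforced by rejection sampling).
#' @param occupancy_prob Probability that a core OTU occurs in a plot
#'   (every core OTU is guaranteed at least one plot).
#' @param abundance_mean Expected total reads of a core OTU in an
#'   occupied plot; each member draws Poisson(`abundance_mean`/S_i)
#'   reads, matching the within-OTU Poisson abundance model.
#' @param doses Per-plot covariate (exogenous nitrogen supply).
#' @param specialist_rate Expected plot-endemic OTUs per unit dose.
#' @param endemic_abundance_mean Expected reads per endemic-OTU member
#'   (at least 1, so singletons arise but are not guaranteed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       r = 8L,
                       k_true = 5L,
                       ancestor_length = 432L,
                       members_per_otu = c(6L, 12L),
                       within_divergence = 0.03,
                       between_divergence = 0.25,
                       occupancy_prob = 0.8,
                       abundance_mean = 75,
                       doses = rep(c(0, 0.85, 2.52, 7.56), each = 2),
                       specialist_rate = 0.5,
                       endemic_abundance_mean = 3) {
  if (within_divergence >= between_divergence / 2) {
    warn(paste("within_divergence >= between_divergence / 2: the planted",
               "identity gap is not guaranteed and recovery may fail",
               "(recovery_check() will flag this via gap_ok)"))
  }
  stopifnot(r == length(doses), all(doses >= 0), specialist_rate >= 0,
            k_true >= 1, ancestor_length >= 1,
            length(members_per_otu) == 2,
            members_per_otu[1] >= 1,
            members_per_otu[2] >= members_per_otu[1])
  structure(list(seed = as.integer(seed), r = as.integer(r),
                 k_true = as.integer(k_true),
                 ancestor_length = as.integer(ancestor_length),
                 members_per_otu = as.integer(members_per_otu),
                 within_divergence = within_divergence,
                 between_divergence = between_divergence,
                 occupancy_prob = occupancy_prob,
                 abundance_mean = abundance_mean,
                 doses = doses,
                 specialist_rate = specialist_rate,
                 endemic_abundance_mean = endemic_abundance_mean),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_sequence <- function(len) {
  paste(sample(BASES, len, replace = TRUE), collapse = "")
}

hamming_frac <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(av != bv)
}

#' Mutate a DNA sequence by exact point substitutions
#'
#' Substitutes exactly `round(divergence * nchar(seq))` positions, chosen
#' without replacement, each to a uniformly random different base.
#'
#' @param seq A/C/G/T string.
#' @param divergence Substitutions per site, in \[0, 1).
#' @param seed Optional seed making the mutation reproducible on its own;
#'   when `NULL` the current RNG stream is used.
#' @return Mutated sequence of the same length.
#' @export
mutate_seq <- function(seq, divergence, seed = NULL) {
  if (divergence < 0 || divergence >= 1) {
    abort("divergence must be in [0, 1)", class = "otunet_data_error")
  }
  run <- function() {
    v <- strsplit(seq, "", fixed = TRUE)[[1]]
    n_mut <- round(divergence * length(v))
    if (n_mut == 0) return(seq)
    pos <- sample.int(length(v), n_mut)
    for (p in pos) v[p] <- sample(setdiff(BASES, v[p]), 1)
    paste(v, collapse = "")
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

# draw a new ancestor at divergence >= min_div from all in `existing`
draw_ancestor <- function(len, existing, min_div, max_tries = 200L) {
  for (t in seq_len(max_tries)) {
    cand <- random_sequence(len)
    if (length(existing) == 0 ||
        all(vapply(existing, hamming_frac, numeric(1), b = cand) >= min_div)) {
      return(cand)
    }
  }
  abort(paste0("could not place an ancestor at divergence >= ", min_div,
               " after ", max_tries, " attempts; use longer ancestors"),
        class = "otunet_data_error")
}

pois_at_least_1 <- function(n, mean) 1L + rpois(n, max(mean - 1, 0))

#' Simulate a planted-OTU amplicon community
#'
#' Generates reads with known OTU structure: core OTU ancestors separated
#' by at least `between_divergence` substitutions/site (rejection
#' sampling), members mutated from their ancestor by at most
#' `within_divergence`/2, Poisson per-member read counts in occupied
#' plots, and dose-scaled plot-endemic OTUs confined to a single home
#' plot. The returned ground truth maps every distinct emitted sequence
#' to its planted OTU.
#'
#' @param cfg A [sim_config()].
#' @return List with `records` (tibble: `read_id`, `plot`, `sequence`),
#'   and `truth`: list with `assignment` (tibble `sequence`, `otu`),
#'   `expected_abundance` (planted-OTU by plot matrix of expected reads),
#'   `endemic_otus` (labels of planted endemics with their home plot) and
#'   `plots`.
#' @export
simulate_community <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(cfg$seed, {
    plots <- sprintf("P%d", seq_len(cfg$r))

    ancestors <- character(0)
    otu_seqs <- list()     # per OTU: member sequences
    otu_label <- character(0)
    home_plot <- character(0)  # NA for core OTUs

    for (i in seq_len(cfg$k_true)) {
      anc <- draw_ancestor(cfg$ancestor_length, ancestors,
                           cfg$between_divergence)
      ancestors <- c(ancestors, anc)
      n_mem <- sample(cfg$members_per_otu[1]:cfg$members_per_otu[2], 1)
      divs <- runif(n_mem, 0, cfg$within_divergence / 2)
      members <- vapply(divs, function(d) mutate_seq(anc, d), character(1))
      otu_seqs[[length(otu_seqs) + 1]] <- unique(members)
      otu_label <- c(otu_label, sprintf("core%02d", i))
      home_plot <- c(home_plot, NA_character_)
    }

    occupancy <- matrix(runif(cfg$k_true * cfg$r) < cfg$occupancy_prob,
                        cfg$k_true, cfg$r)
    for (i in seq_len(cfg$k_true)) {
      if (!any(occupancy[i, ])) occupancy[i, sample.int(cfg$r, 1)] <- TRUE
    }

    # dose-scaled plot-endemic OTUs
    n_end <- rpois(cfg$r, cfg$specialist_rate * cfg$doses)
    for (q in seq_len(cfg$r)) {
      for (e in seq_len(n_end[q])) {
        anc <- draw_ancestor(cfg$ancestor_length, ancestors,
                             cfg$between_divergence)
        ancestors <- c(ancestors, anc)
        n_mem <- sample(1:2, 1)
        divs <- runif(n_mem, 0, cfg$within_divergence / 2)
        members <- vapply(divs, function(d) mutate_seq(anc, d), character(1))
        otu_seqs[[length(otu_seqs) + 1]] <- unique(members)
        otu_label <- c(otu_label,
                       sprintf("endemic_%s_%02d", plots[q], e))
        home_plot <- c(home_plot, plots[q])
      }
    }

    k_all <- length(otu_seqs)
    expected <- matrix(0, k_all, cfg$r, dimnames = list(otu_label, plots))
    recs <- vector("list", 0)
    for (i in seq_len(k_all)) {
      members <- otu_seqs[[i]]
      S_i <- length(members)
      active <- if (is.na(home_plot[i])) which(occupancy[i, ])
                else match(home_plot[i], plots)
      for (q in active) {
        if (is.na(home_plot[i])) {
          counts <- rpois(S_i, cfg$abundance_mean / S_i)
          expected[i, q] <- cfg$abundance_mean
        } else {
          counts <- pois_at_least_1(S_i, cfg$endemic_abundance_mean)
          expected[i, q] <- S_i * max(cfg$endemic_abundance_mean, 1)
        }
        for (j in which(counts > 0)) {
          recs[[length(recs) + 1]] <- tibble::tibble(
            plot = plots[q], sequence = members[j], otu = otu_label[i],
            .rows = counts[j])
        }
      }
    }
    reads <- dplyr::bind_rows(recs)
    if (nrow(reads) == 0) abort("simulation produced no reads",
                                class = "otunet_data_error")
    reads <- reads[order(reads$plot, reads$otu, reads$sequence), ]
    reads$read_id <- sprintf("read%06d", seq_len(nrow(reads)))

    assignment <- dplyr::distinct(reads, .data$sequence, .data$otu)
    endemics <- tibble::tibble(otu = otu_label[!is.na(home_plot)],
                               home_plot = home_plot[!is.na(home_plot)])
    list(records = tibble::tibble(read_id = reads$read_id,
                                  plot = reads$plot,
                                  sequence = reads$sequence),
         truth = list(assignment = assignment,
                      expected_abundance = expected,
                      endemic_otus = endemics,
                      plots = plots))
  })
}

#' Run the full pipeline on a simulated community and score recovery
#'
#' Dereplicates the simulated reads, scans the threshold grid, scores it
#' with the network AIC, selects the optimal threshold and compares the
#' recovered partition to the planted one with the adjusted Rand index.
#' Also reports whether the planted structure is recoverable at all: the
#' realised maximum within-OTU distance must fall below the realised
#' minimum between-OTU distance (a positive identity gap). When there is
#' no gap the report flags it instead of claiming recovery.
#'
#' @param cfg A [sim_config()].
#' @param grid Similarity grid (default 74:99).
#' @param model Abundance model for the weighted AIC.
#' @param weighted Select on the weighted (default) or binary AIC.
#' @return One-row tibble: `optimal_threshold`, `k_selected`, `k_planted`
#'   (planted OTUs with at least one read), `ari`, `gap_ok`,
#'   `gap_low_pct`/`gap_high_pct` (the realised identity gap in percent),
#'   `S` (sequence types), `n_reads`.
#' @export
recovery_check <- function(cfg, grid = 74:99, model = "poisson",
                           weighted = TRUE) {
  sim <- simulate_community(cfg)
  tab <- dereplicate(sim$records, plots = sim$truth$plots)
  dm <- compute_distances(tab)
  scan <- cluster_scan(dm, grid, tab)
  curve <- aic_curve(tab, scan, model = model, weighted = weighted)
  opt <- select_optimal(curve)
  part <- scan[[match(opt, vapply(scan, `[[`, numeric(1), "threshold_pct"))]]

  truth_otu <- sim$truth$assignment$otu[
    match(tab$sequence, sim$truth$assignment$sequence)]
  ari <- mclust::adjustedRandIndex(part$assignment, truth_otu)

  same <- outer(truth_otu, truth_otu, `==`)
  dmat <- as.matrix(dm)
  ut <- upper.tri(dmat)
  within_d <- dmat[ut & same]
  between_d <- dmat[ut & !same]
  gap_low <- if (length(between_d)) min(between_d) else NA_real_
  gap_high <- if (length(within_d)) max(within_d) else 0
  gap_ok <- is.na(gap_low) || gap_high < gap_low

  tibble::tibble(optimal_threshold = opt,
                 k_selected = part$k,
                 k_planted = length(unique(truth_otu)),
                 ari = ari,
                 gap_ok = gap_ok,
                 gap_low_pct = 100 * (1 - gap_low),
                 gap_high_pct = 100 * (1 - gap_high),
                 S = nrow(tab),
                 n_reads = nrow(sim$records))
}
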