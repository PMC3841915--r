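test_that("network construction counts links, sizes and summed abundances", {
  # 1 OTU of 2 types, abundance rows [3,0] and [1,2] over 2 plots
  net <- net_fixture(matrix(c(3L, 1L, 0L, 2L), 2, 2), c(1, 1))
  expect_equal(net$S_i, 2L)
  expect_equal(unname(net$L), matrix(c(2, 1), 1, 2))
  expect_equal(unname(net$a_dot), matrix(c(4, 2), 1, 2))
  expect_equal(net$L_total, 3)

  # every type its own OTU
  net2 <- net_fixture(matrix(c(3L, 1L, 0L, 2L), 2, 2), c(1, 2))
  expect_true(all(net2$L %in% 0:1))
  expect_true(all(net2$S_i == 1))

  # single plot
  net3 <- net_fixture(matrix(c(2L, 0L, 1L), 3, 1), c(1, 1, 1))
  expect_equal(unname(net3$L), matrix(2, 1, 1))

  tab <- make_table(c("AAAA", "CCCC"), matrix(c(1L, 1L), 2, 1))
  expect_error(build_network(tab, as_partition(c(1, 1, 2))),
               class = "otunet_data_error")
})

test_that("link probability and binary log-likelihood match hand values", {
  # S_i = 4, L = 3 in plot 1; L = 0 in plot 2; L = 4 in plot 3
  abund <- cbind(c(1L, 1L, 1L, 0L), 0L, 1L)
  net <- net_fixture(abund, rep(1, 4))
  expect_equal(link_probability(net, 1, 1), 0.75)
  expect_equal(link_probability(net, 1, 2), 0)
  expect_equal(link_probability(net, 1, 3), 1)
  # 3*ln(0.75) + 1*ln(0.25), frozen after oracle verification
  o <- oracle_network_scores(abund, rep(1, 4))
  expect_equal(o$ll_binary_mat[1, 1], -2.2493406, tolerance = 1e-7)
  expect_equal(binary_ll(net, 1, 1), o$ll_binary_mat[1, 1])
  expect_equal(binary_ll(net, 1, 1), 3 * log(0.75) + log(0.25))
  expect_equal(binary_ll(net, 1, 2), 0)  # 0 log 0 rule at L = 0
  expect_equal(binary_ll(net, 1, 3), 0)  # p = 1
})

test_that("verbatim printed sign flips the miss term positive", {
  abund <- cbind(c(1L, 1L, 1L, 0L))
  net <- net_fixture(abund, rep(1, 4))
  expect_equal(binary_ll(net, 1, 1, verbatim_sign = TRUE),
               3 * log(0.75) - log(0.25))
  expect_gt(binary_ll(net, 1, 1, verbatim_sign = TRUE),
            binary_ll(net, 1, 1))
  o <- oracle_network_scores(abund, rep(1, 4), verbatim_sign = TRUE)
  expect_equal(binary_aic(net, verbatim_sign = TRUE), o$aic_binary)
  # degenerate cells are unaffected by the sign convention
  net2 <- net_fixture(cbind(c(1L, 1L)), c(1, 1))
  expect_equal(binary_ll(net2, 1, 1, verbatim_sign = TRUE), 0)
})

test_that("binary AIC matches hand-computed and closed-form cases", {
  # k=1, r=1, S=2, L=1: penalty 6, LL = 2 ln(1/2)
  net <- net_fixture(cbind(c(1L, 0L)), c(1, 1))
  expect_equal(binary_aic(net), 8.7725887, tolerance = 1e-7)
  expect_equal(binary_aic(net), oracle_network_scores(
    cbind(c(1L, 0L)), c(1, 1))$aic_binary)

  # finest partition: every p is 0 or 1 so total binary LL = 0 exactly
  withr::with_seed(2, {
    abund <- matrix(rpois(12, 2), 4, 3); abund[rowSums(abund) == 0, 1] <- 1L
  })
  finest <- net_fixture(abund, 1:4)
  expect_identical(sum(otunet:::binary_ll_matrix(finest)), 0)
  expect_equal(binary_aic(finest), 2 * 4 * 3 + 2 * 4)

  # k=1, all members in all plots: LL = 0, AIC = 2r + 2S
  full <- net_fixture(matrix(1L, 3, 2), c(1, 1, 1))
  expect_equal(binary_aic(full), 2 * 2 + 2 * 3)
})

test_that("abundance log-likelihoods match hand values for both models", {
  net <- net_fixture(cbind(c(3L, 1L)), c(1, 1))
  # poisson, lambda = 2: [3 ln2 - 2 - ln6] + [ln2 - 2]
  o_p <- oracle_log_pois(3, 2) + oracle_log_pois(1, 2)
  expect_equal(o_p, -3.0191707, tolerance = 1e-7)
  expect_equal(abundance_ll(net, 1, 1, "poisson"), o_p)
  # binomial, size 4, p = 1/2: 2 * ln(4 * 0.5^4)
  o_b <- oracle_log_binom(3, 4, 0.5) + oracle_log_binom(1, 4, 0.5)
  expect_equal(o_b, -2.7725887, tolerance = 1e-7)
  expect_equal(abundance_ll(net, 1, 1, "binomial"), o_b)
  # single-member OTU: degenerate, contribution 0 under either model
  net1 <- net_fixture(cbind(5L), 1)
  expect_equal(abundance_ll(net1, 1, 1, "poisson"),
               dpois(5, 5, log = TRUE))  # poisson is not degenerate at S_i=1
  expect_equal(abundance_ll(net1, 1, 1, "binomial"), 0)
  # absent OTU-plot cell contributes 0
  net0 <- net_fixture(cbind(c(2L, 1L), c(0L, 0L)), c(1, 1))
  expect_equal(abundance_ll(net0, 1, 2, "poisson"), 0)
  expect_equal(abundance_ll(net0, 1, 2, "binomial"), 0)
  expect_error(abundance_ll(net, 1, 1, "gamma"))
})

test_that("weighted AIC combines both likelihoods with the 4kr penalty", {
  # k=1, r=1, S=2, L=2, abundances [3,1], poisson
  net <- net_fixture(cbind(c(3L, 1L)), c(1, 1))
  expect_equal(weighted_aic(net, "poisson"), 14.0383415, tolerance = 1e-7)
  o <- oracle_network_scores(cbind(c(3L, 1L)), c(1, 1))
  expect_equal(weighted_aic(net, "poisson"), o$aic_weighted)
})

test_that("weighted minus binary AIC equals 2kr - 2*sum(abundance LL) exactly", {
  withr::with_seed(31, {
    for (case in 1:20) {
      cs <- random_network_case()
      net <- net_fixture(cs$abund, cs$assignment)
      for (model in c("poisson", "binomial")) {
        lhs <- weighted_aic(net, model) - binary_aic(net)
        rhs <- 2 * net$k * net$r -
          2 * sum(otunet:::abundance_ll_matrix(net, model))
        expect_equal(lhs, rhs, tolerance = 1e-12)
      }
      # sign contract: every contribution is non-positive
      expect_true(all(otunet:::binary_ll_matrix(net) <= 0))
      expect_true(all(otunet:::abundance_ll_matrix(net, "poisson") <= 1e-12))
      expect_true(all(otunet:::abundance_ll_matrix(net, "binomial") <= 1e-12))
      expect_gte(binary_aic(net), 2 * net$k * net$r + 2 * net$S)
    }
  })
})

test_that("equal allocation maximises the poisson contribution", {
  # over all integer reallocations of the same total among S_i members
  compositions <- function(total, parts) {
    if (parts == 1) return(matrix(total, 1, 1))
    do.call(rbind, lapply(0:total, function(x)
      cbind(x, compositions(total - x, parts - 1))))
  }
  for (S_i in 2:3) {
    for (total in seq(S_i, 8, by = S_i)) {
      alloc <- compositions(total, S_i)
      ll <- apply(alloc, 1, function(a) {
        net <- net_fixture(cbind(as.integer(a)), rep(1, S_i))
        abundance_ll(net, 1, 1, "poisson")
      })
      equal_row <- which(apply(alloc, 1, function(a) all(a == total / S_i)))
      expect_equal(max(ll), ll[equal_row], tolerance = 1e-12)
    }
  }
})

test_that("AIC curve selection follows the argmin and tie rules", {
  withr::with_seed(8, {
    anc1 <- random_dna(60); anc2 <- mutate_seq(anc1, 0.4)
    seqs <- unique(c(vapply(1:3, function(i) mutate_seq(anc1, 0.02),
                            character(1)),
                     vapply(1:3, function(i) mutate_seq(anc2, 0.02),
                            character(1))))
    abund <- matrix(rpois(length(seqs) * 3, 5), length(seqs), 3)
    abund[rowSums(abund) == 0, 1] <- 1L
  })
  tab <- make_table(seqs, abund)
  dm <- compute_distances(tab)

  # grid of one threshold: that threshold is optimal
  scan1 <- cluster_scan(dm, 88, tab)
  curve1 <- aic_curve(tab, scan1)
  expect_equal(select_optimal(curve1), 88)

  # identical partitions at neighbouring thresholds tie to the lower one
  scan2 <- cluster_scan(dm, c(85, 86), tab)
  expect_equal(scan2[[1]]$assignment, scan2[[2]]$assignment)
  curve2 <- aic_curve(tab, scan2)
  expect_equal(curve2$aic_weighted[1], curve2$aic_weighted[2])
  expect_equal(select_optimal(curve2), 85)

  # adding the constant 2S to every threshold cannot change the argmin
  curve <- aic_curve(tab, cluster_scan(dm, 74:99, tab))
  shifted <- curve$aic_weighted - 2 * nrow(tab)
  expect_equal(which.min(shifted), which.min(curve$aic_weighted))
  expect_equal(glance(curve)$optimal_threshold, select_optimal(curve))
  expect_s3_class(autoplot(curve), "ggplot")
})

test_that("curve rows agree with the naive oracle at every threshold", {
  withr::with_seed(13, {
    seqs <- replicate(8, random_dna(30))
    while (anyDuplicated(seqs)) seqs <- replicate(8, random_dna(30))
    abund <- matrix(rpois(8 * 4, 3), 8, 4)
    abund[rowSums(abund) == 0, 1] <- 1L
  })
  tab <- make_table(seqs, abund)
  dm <- compute_distances(tab)
  scan <- cluster_scan(dm, c(74, 85, 99), tab)
  curve <- aic_curve(tab, scan, model = "binomial")
  for (i in seq_len(nrow(curve))) {
    o <- oracle_network_scores(st_abundance(tab), scan[[i]]$assignment,
                               model = "binomial")
    expect_equal(curve$aic_binary[i], o$aic_binary, tolerance = 1e-9)
    expect_equal(curve$aic_weighted[i], o$aic_weighted, tolerance = 1e-9)
  }
})
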