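test_that("intensity statistics separate cross and self terms", {
  expect_equal(intensity_stats(diag(4)),
               c(mean_chi = 0, max_chi = 0, mean_self = 1, max_self = 1))
  chi <- matrix(c(1, 0.1, 0.3, 1), 2, 2)  # column-major: chi[2,1]=0.1, chi[1,2]=0.3
  st <- intensity_stats(chi)
  expect_equal(st[["mean_chi"]], 0.2)
  expect_equal(st[["max_chi"]], 0.3)
  expect_equal(st[["mean_self"]], 1)
})

test_that("selectivity is an inverse participation ratio over partners", {
  # one nonzero partner: maximal selectivity
  chi <- diag(3); chi[1, 2] <- 0.4
  g <- selectivity(chi)$g
  expect_equal(g[[1]], 1)

  # uniform over N-1 = 4 partners: minimal selectivity
  chi <- matrix(0.2, 5, 5); diag(chi) <- 1
  sel <- selectivity(chi)
  expect_equal(sel$g, rep(0.25, 5))
  expect_equal(sel$s_in, 0.25)
  expect_equal(sel$s_out, 0.25)

  # arithmetic case: row (0.3, 0.1)
  chi <- diag(3); chi[1, 2] <- 0.3; chi[1, 3] <- 0.1
  expect_equal(selectivity(chi)$g[[1]], 0.625)

  # zero rows are excluded and counted; all-zero is undefined
  expect_equal(selectivity(chi)$n_excluded_in, 2L)
  expect_warning(sel0 <- selectivity(diag(3)), "undefined")
  expect_true(is.na(sel0$s_in))
})

test_that("selectivities live in [1/(N-1), 1] over random susceptibility patterns", {
  set.seed(5)
  for (k in 1:10) {
    N <- sample(3:12, 1)
    chi <- matrix(rexp(N * N), N, N)
    chi[sample(N * N, N)] <- 0
    sel <- suppressWarnings(selectivity(chi))
    ok <- !is.na(sel$g)
    expect_true(all(sel$g[ok] >= 1 / (N - 1) - 1e-12 & sel$g[ok] <= 1 + 1e-12))
  }
})

test_that("locality kernel sums inverse threshold products over shared regulators", {
  # M = 2; RNAs i, j share miRNA 1 with mu0 4 and 8
  net <- interaction_network(c("ri", "rj"), c("ma", "mb"),
                             data.frame(rna = c(1L, 2L, 1L),
                                        mirna = c(1L, 1L, 2L),
                                        mode = "kmer"))
  p <- kinetic_params(net, bh = bh_scenario("low"), mu0_base = 2)
  p$mu0_edge <- c(4, 8, 5)  # manual thresholds for the arithmetic check
  K <- as.matrix(locality_matrix(net, p))
  expect_equal(K[1, 2], 0.5 * 1 / 32)
  expect_equal(K, t(K))

  # two shared miRNAs, all thresholds 4
  net2 <- interaction_network(c("ri", "rj"), c("ma", "mb"),
                              data.frame(rna = c(1L, 2L, 1L, 2L),
                                         mirna = c(1L, 1L, 2L, 2L),
                                         mode = "kmer"))
  p2 <- kinetic_params(net2, bh = bh_scenario("low"), mu0_base = 2)
  K2 <- as.matrix(locality_matrix(net2, p2))
  expect_equal(K2[1, 2], 0.5 * 2 / 16)
})

test_that("locality correlation is Pearson over ordered pairs with exact limits", {
  net <- random_test_network(10, 3, 20, seed = 55)
  p <- kinetic_params(net, b = 8, beta = 20)
  K <- as.matrix(locality_matrix(net, p))
  chi <- 3.7 * K  # perfectly linear
  expect_equal(locality_correlation(chi, K), 1)

  chi2 <- matrix(0, 3, 3); K3 <- matrix(0, 3, 3)
  chi2[lower.tri(chi2) | upper.tri(chi2)] <- c(1, 2, 3, 4, 5, 6)
  K3[lower.tri(K3) | upper.tri(K3)] <- c(6, 5, 4, 3, 2, 1)
  expect_equal(locality_correlation(chi2, K3), -1)

  # invariant to positive affine rescaling of either argument
  fit <- crosstalk_fit(net, p)
  r1 <- locality_correlation(fit$chi, K)
  r2 <- locality_correlation(0.2 * fit$chi + 1e-6, K)
  r3 <- locality_correlation(fit$chi, 14 * K + 2)
  expect_equal(r1, r2)
  expect_equal(r1, r3)

  expect_warning(r0 <- locality_correlation(matrix(1, 3, 3), K3), "undefined")
  expect_true(is.na(r0))
})

test_that("asymmetry index ranges from symmetric 0 to one-directional 1", {
  chi <- matrix(c(1, 0.2, 0.2, 1), 2, 2)
  expect_equal(asymmetry_index(chi), 0)

  chi <- matrix(c(1, 0, 0.5, 1), 2, 2)  # chi_12 = 0.5, chi_21 = 0
  expect_equal(asymmetry_index(chi), 1)

  # v-motif with unequal transcription rates is measurably asymmetric
  net <- make_motif("v_motif")$network
  p <- kinetic_params(net, b = c(4, 24), beta = 25)
  fit <- crosstalk_fit(net, p)
  expect_gt(asymmetry_index(fit$chi), 0)

  expect_warning(a0 <- asymmetry_index(diag(3)), "undefined")
  expect_true(is.na(a0))
})

test_that("expression CV at zero miRNA transcription equals the CV of b", {
  net <- random_test_network(15, 4, 30, seed = 23)
  b <- sample_transcription_rates(15, 8, 0.6, seed = 44)
  p <- kinetic_params(net, b = b, beta = 0)
  st <- solve_steady_state(net, p)
  expect_equal(expression_cv(st), sd(b) / mean(b))
  expect_equal(expression_cv(rep(4, 10)), 0)
})

test_that("sextile persistence distinguishes identical, reversed and random rankings", {
  n <- 120
  x <- sort(rexp(n), decreasing = TRUE)
  same <- sextile_persistence(x, x, seed = 1, n_perm = 200)
  expect_equal(same$fractions, rep(1, 6))
  expect_equal(same$overall, 1)

  rev_res <- sextile_persistence(x, rev(x), seed = 1, n_perm = 200)
  expect_equal(rev_res$fractions[1], 0)

  set.seed(9)
  indep <- sextile_persistence(rexp(n), rexp(n), seed = 2, n_perm = 500)
  # independent rankings stay near the chance level 1/6 (3 binomial SEs)
  se_bin <- sqrt((1 / 6) * (5 / 6) / (n / 6))
  expect_true(all(abs(indep$fractions - 1 / 6) < 3 * se_bin))
  expect_true(all(abs(indep$chance - 1 / 6) < 0.02))

  # bins partition the pairs with near-equal sizes
  expect_equal(sum(indep$bin_sizes), n)
  expect_lte(diff(range(indep$bin_sizes)), 1)
  odd <- sextile_persistence(rexp(100), rexp(100), seed = 3, n_perm = 50)
  expect_equal(sum(odd$bin_sizes), 100)
  expect_lte(diff(range(odd$bin_sizes)), 1)

  expect_error(sextile_persistence(rexp(10), rexp(12)), "do not match")
})

test_that("susceptible region brackets the appreciable-crosstalk window", {
  grid <- c(1, 2, 4, 8, 16)
  expect_equal(susceptible_region(grid, c(0, 0, 1, 0, 0)),
               c(beta_low = 4, beta_high = 4))
  expect_equal(susceptible_region(grid, rep(0.3, 5)),
               c(beta_low = 1, beta_high = 16))
  expect_warning(r <- susceptible_region(grid, rep(0, 5)), "undefined")
  expect_true(all(is.na(r)))
  bell <- c(0.001, 0.2, 1, 0.3, 0.002)
  expect_equal(susceptible_region(grid, bell),
               c(beta_low = 2, beta_high = 8))
})
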