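test_that("pairwise dominant FST is zero for identical populations and
           near one for fixed differences", {
  set.seed(101)
  # identical underlying frequencies in both populations
  calls <- matrix(rbinom(2 * 100 * 60, 1, rep(runif(60, .2, .8),
                                              each = 200)),
                  200, 60)
  mk <- toy_markers(calls, rep(c("a", "b"), 100))
  fq <- estimate_allele_frequencies(mk, "sqrt")
  m <- pairwise_fst_dominant(fq)
  expect_lt(abs(m["a", "b"]), 0.02)
  expect_equal(diag(unclass(m)), c(a = 0, b = 0))
  expect_equal(m["a", "b"], m["b", "a"])

  # near-fixed opposite frequencies
  calls2 <- rbind(matrix(rbinom(200 * 100, 1, 1 - (1 - 0.98)^2), 200, 100),
                  matrix(rbinom(200 * 100, 1, 1 - (1 - 0.02)^2), 200, 100))
  mk2 <- toy_markers(calls2, rep(c("a", "b"), each = 200))
  m2 <- pairwise_fst_dominant(estimate_allele_frequencies(mk2, "sqrt"))
  expect_gt(m2["a", "b"], 0.9)
})

test_that("dominant FST recovers an island-model target and is invariant
           to population order", {
  set.seed(102)
  env <- simulate_env()
  ests <- replicate(10, {
    sim <- simulate_aflp(env, n_loci = 300)
    fq <- estimate_allele_frequencies(sim$markers, "sqrt")
    landgen:::wc_theta_dominant(1 - fq$band_freq, fq$n_scored)
  })
  expect_equal(mean(ests), 0.15, tolerance = 0.25)

  sim <- simulate_aflp(env, n_loci = 200)
  fq <- estimate_allele_frequencies(sim$markers, "sqrt")
  m <- pairwise_fst_dominant(fq)
  perm <- sample(rownames(m))
  fq2 <- fq
  fq2$q_hat <- fq$q_hat[, perm]; fq2$band_freq <- fq$band_freq[, perm]
  fq2$n_scored <- fq$n_scored[, perm]; fq2$populations <- perm
  m2 <- pairwise_fst_dominant(fq2)
  expect_equal(unclass(m2)[rownames(m), colnames(m)], unclass(m),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("refugium scores are off-diagonal row means with tie handling", {
  m <- structure(matrix(c(0, .1, .3, .1, 0, .2, .3, .2, 0), 3, 3,
                        dimnames = list(c("p1", "p2", "p3"),
                                        c("p1", "p2", "p3"))),
                 class = c("fst_matrix", "matrix"), source = "dominant")
  rs <- mean_population_fst(m)
  expect_equal(rs$mean_fst, c(0.2, 0.15, 0.25))
  expect_equal(attr(rs, "candidate"), "p3")
  # identity: mean of scores equals off-diagonal mean
  set.seed(103)
  r <- matrix(runif(25), 5, 5); r <- (r + t(r)) / 2; diag(r) <- 0
  dimnames(r) <- list(paste0("p", 1:5), paste0("p", 1:5))
  rs2 <- mean_population_fst(structure(r, class = c("fst_matrix", "matrix"),
                                       source = "dominant"))
  expect_equal(mean(rs2$mean_fst), mean(r[upper.tri(r)]))
  # equal off-diagonals: tie flagged
  e <- matrix(0.2, 3, 3); diag(e) <- 0
  dimnames(e) <- list(c("a", "b", "c"), c("a", "b", "c"))
  rs3 <- mean_population_fst(structure(e, class = c("fst_matrix", "matrix"),
                                       source = "dominant"))
  expect_true(attr(rs3, "tie"))
})

test_that("AMOVA components match a hand-computed decomposition", {
  # 6 individuals, 2 populations; profiles chosen so sums of squares are
  # tractable by hand via pairwise squared Euclidean distances
  calls <- rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 1),
                 c(0, 0, 1), c(0, 1, 1), c(0, 0, 0))
  mk <- toy_markers(calls, rep(c("a", "b"), each = 3))
  am <- amova_phist(mk, n_permutations = 0)
  d2 <- as.matrix(dist(calls))^2
  ss_total <- sum(d2[upper.tri(d2)]) / 6
  ss_w <- sum(d2[1:3, 1:3][upper.tri(d2[1:3, 1:3])]) / 3 +
    sum(d2[4:6, 4:6][upper.tri(d2[4:6, 4:6])]) / 3
  ms_a <- (ss_total - ss_w) / 1
  ms_w <- ss_w / 4
  s2a <- (ms_a - ms_w) / 3
  expect_equal(am$sigma2_within, ms_w)
  expect_equal(am$sigma2_among, s2a)
  expect_equal(am$phi_st, s2a / (s2a + ms_w))

  # perfect between-population structure
  calls2 <- rbind(matrix(rep(c(1, 0, 1, 0, 1), 3), 3, 5, byrow = TRUE),
                  matrix(rep(c(0, 1, 0, 1, 0), 3), 3, 5, byrow = TRUE))
  mk2 <- toy_markers(calls2, rep(c("a", "b"), each = 3))
  expect_equal(amova_phist(mk2, n_permutations = 0)$phi_st, 1)
  expect_error(amova_phist(mk2, n_permutations = 5), "10")
})

test_that("AMOVA on shuffled labels is null-calibrated", {
  set.seed(104)
  sim <- simulate_aflp(simulate_env(n_pop = 4), n_per = 10, n_loci = 60)
  mk <- sim$markers
  shuffled <- setNames(sample(mk$population_of), mk$individual_ids)
  ps <- phis <- numeric(20)
  for (r in 1:20) {
    sh <- setNames(sample(mk$population_of), mk$individual_ids)
    am <- amova_phist(mk, n_permutations = 49, groups = sh)
    ps[r] <- am$p; phis[r] <- am$phi_st
  }
  expect_lt(abs(mean(phis)), 0.02)
  expect_gt(mean(ps), 0.25)  # p roughly uniform, not piled at 0
  expect_lt(mean(ps < 0.05), 0.3)
})

test_that("sequence-mode pairwise Phi-ST equals the two-population AMOVA", {
  set.seed(105)
  a1 <- simulate_coalescent_alignment(8, 4, sites = 200, population = "x")
  a2 <- simulate_coalescent_alignment(8, 4, sites = 200, population = "y",
                                      prefix = "t")
  ids <- c(a1$sample_ids, a2$sample_ids)
  seqs <- c(a1$sequences, a2$sequences)
  aln <- aligned_sequence_set(ids, seqs,
                              setNames(c(a1$population_of,
                                         a2$population_of), ids))
  m <- pairwise_phist_sequence(aln)
  am <- amova_phist(aln, n_permutations = 0)
  expect_equal(m["x", "y"], am$phi_st, tolerance = 1e-12)
})

test_that("cluster search finds planted structure and resists
           overfitting", {
  set.seed(106)
  sim <- simulate_aflp(simulate_env(n_pop = 2), n_per = 30, n_loci = 200,
                       background_fst = 0.5)
  cl <- find_clusters(sim$markers, K_range = 1:5)
  expect_equal(cl$best_K, 2L)
  truth <- as.integer(factor(sim$markers$population_of))
  agree <- max(mean(cl$assignments == truth),
               mean(cl$assignments == 3 - truth))
  expect_gte(agree, 0.95)

  sim2 <- simulate_aflp(simulate_env(n_pop = 2), n_per = 30, n_loci = 200,
                        background_fst = 0.005)
  expect_equal(find_clusters(sim2$markers, K_range = 1:5)$best_K, 1L)

  # duplicated rows always co-assign
  mk <- sim$markers
  mk$calls[2, ] <- mk$calls[1, ]
  cl2 <- find_clusters(mk, K_range = 2)
  expect_equal(unname(cl2$all_assignments[["2"]][1]),
               unname(cl2$all_assignments[["2"]][2]))
  expect_error(find_clusters(sim$markers, K_range = 1:70), "K_max")
})

test_that("discriminant axes separate clusters and match a direct
           eigen-decomposition", {
  set.seed(107)
  sim <- simulate_aflp(simulate_env(n_pop = 3), n_per = 15, n_loci = 150,
                       background_fst = 0.5)
  cl <- find_clusters(sim$markers, K_range = 3)
  grp <- factor(sim$markers$population_of)
  ax <- dapc_axes(cl, assignments = grp)
  expect_equal(sum(ax$var_fraction), 1)
  expect_equal(ncol(ax$coordinates), 2L)

  # oracle: eigenvalues of W^{-1} B reproduce the axis variance ratios
  X <- cl$scores
  gm <- colMeans(X)
  B <- W <- matrix(0, ncol(X), ncol(X))
  for (g in levels(grp)) {
    Xg <- X[grp == g, , drop = FALSE]
    cg <- colMeans(Xg)
    B <- B + nrow(Xg) * tcrossprod(cg - gm)
    W <- W + crossprod(scale(Xg, center = cg, scale = FALSE))
  }
  ev <- sort(Re(eigen(solve(W) %*% B)$values), decreasing = TRUE)[1:2]
  expect_equal(ax$var_fraction, ev / sum(ev), tolerance = 1e-6)

  # a perfectly separated pair yields non-overlapping LD1 scores
  sim2 <- simulate_aflp(simulate_env(n_pop = 2), n_per = 10, n_loci = 100,
                        background_fst = 0.8)
  cl2 <- find_clusters(sim2$markers, K_range = 2)
  ax2 <- dapc_axes(cl2, assignments = factor(sim2$markers$population_of))
  g <- factor(sim2$markers$population_of)
  r1 <- range(ax2$coordinates[g == levels(g)[1], 1])
  r2 <- range(ax2$coordinates[g == levels(g)[2], 1])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])
  expect_error(dapc_axes(cl2, assignments = factor(rep("z", 20))), "2")
})
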