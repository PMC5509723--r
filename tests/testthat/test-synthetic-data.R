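test_that("coalescent simulator is consistent with Watterson's estimator
           and neutral Tajima's D", {
  set.seed(71)
  reps <- 1000
  S <- D <- numeric(reps)
  a1 <- sum(1 / 1:19)
  for (r in seq_len(reps)) {
    st <- landgen:::sim_replicate_stats(20, theta = 5)
    S[r] <- st$S
    D[r] <- if (st$S >= 1) tajimas_d(20, st$S, st$k_bar) else NA
  }
  expect_equal(mean(S) / a1, 5, tolerance = 0.05)
  expect_lt(abs(mean(D, na.rm = TRUE)), 0.1)
})

test_that("pairwise and Watterson estimators both recover theta", {
  set.seed(72)
  reps <- 1000
  kb <- SS <- numeric(reps)
  for (r in seq_len(reps)) {
    st <- landgen:::sim_replicate_stats(20, theta = 5)
    kb[r] <- st$k_bar; SS[r] <- st$S
  }
  expect_equal(mean(kb), 5, tolerance = 0.10)
  expect_equal(mean(SS) / sum(1 / 1:19), 5, tolerance = 0.10)
})

test_that("coalescent tree height for n = 2 has mean one", {
  set.seed(73)
  h <- replicate(5000, landgen:::sim_genealogy(2)$tmrca)
  expect_equal(mean(h), 1, tolerance = 0.05)
})

test_that("sudden-expansion spectra are unimodal with mode near tau", {
  set.seed(74)
  good <- 0
  for (r in 1:30) {
    st <- landgen:::sim_replicate_stats(50, theta = 50,
                                        demography = "sudden-expansion",
                                        t_expansion = 2 / 50,
                                        growth_factor = 100,
                                        genotypes = TRUE)
    sp <- landgen:::mismatch_spectrum_from_pairs(
      landgen:::pair_diffs_binary(st$X), 50)
    mode <- as.integer(names(which.max(sp$counts)))
    if (mode >= 0 && mode <= 5) good <- good + 1
  }
  expect_gte(good / 30, 0.8)
})

test_that("alignment generator respects the requested length and errors
           when sites are too few", {
  set.seed(75)
  aln <- simulate_coalescent_alignment(10, 3, sites = 150)
  expect_equal(aln$k, 150L)
  expect_error(simulate_coalescent_alignment(40, 80, sites = 5),
               "exceed")
})

test_that("generators are deterministic given the seed", {
  set.seed(76); e1 <- simulate_env()
  set.seed(76); e2 <- simulate_env()
  expect_identical(e1, e2)
  set.seed(77); s1 <- simulate_aflp(e1, n_loci = 50)
  set.seed(77); s2 <- simulate_aflp(e1, n_loci = 50)
  expect_identical(s1$markers$calls, s2$markers$calls)
  set.seed(78); a1 <- simulate_coalescent_alignment(6, 2, sites = 100)
  set.seed(78); a2 <- simulate_coalescent_alignment(6, 2, sites = 100)
  expect_identical(a1$sequences, a2$sequences)
})

test_that("dominant phenotype frequencies match 1-(1-p)^2 at large n", {
  set.seed(79)
  env <- simulate_env(n_pop = 3)
  sim <- simulate_aflp(env, n_per = 4000, n_loci = 30)
  shown <- sapply(rownames(env), function(p)
    colMeans(sim$markers$calls[sim$markers$population_of == p, ]))
  expect_equal(as.vector(shown), as.vector(1 - (1 - sim$p_pop)^2),
               tolerance = 0.03)
})

test_that("environmental generator honours gradient and noise settings", {
  set.seed(80)
  env0 <- simulate_env(n_var = 2, noise_sd = 0)
  proj <- scale(env0$lon + env0$lat)[, 1]
  expect_equal(cor(env0$env1, proj), 1, tolerance = 1e-12)
  env1 <- simulate_env(n_var = 2, gradient = 0)
  expect_lt(abs(cor(env1$env1, proj)), 1)  # no deterministic tie
})

test_that("zero-coefficient plants are indistinguishable from neutral
           loci", {
  set.seed(81)
  env <- simulate_env()
  sim <- simulate_aflp(env, n_loci = 200,
                       planted = data.frame(locus = 1:5, variable = "env1",
                                            coeff = 0))
  fq <- estimate_allele_frequencies(sim$markers, "sqrt")
  fst_planted <- landgen:::wc_theta_dominant(
    1 - fq$band_freq[1:5, , drop = FALSE], fq$n_scored[1:5, , drop = FALSE])
  # a coeff-0 plant collapses to identical frequencies in all populations,
  # so its differentiation estimate sits at or below the background
  expect_lt(fst_planted, 0.15)
})

test_that("a planted high-FST locus carries its stated differentiation", {
  set.seed(82)
  env <- simulate_env()
  sim <- simulate_aflp(env, n_loci = 20)
  mk <- plant_fst_locus(sim$markers, locus = 3, fst = 0.6)
  pj <- attr(mk, "planted_p")
  expect_equal(var(pj) / (mean(pj) * (1 - mean(pj))), 0.6, tolerance = 0.15)
})
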