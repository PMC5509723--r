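test_that("square-root estimator and zero-class boundary behave as
           documented", {
  calls <- cbind(L1 = c(rep(0, 4), rep(1, 6)),  # 4 of 10 absent
                 L2 = rep(1, 10))               # every individual banded
  mk <- toy_markers(calls, rep("a", 10))
  fq <- estimate_allele_frequencies(mk, "sqrt")
  expect_equal(fq$q_hat["L1", "a"], sqrt(0.4), tolerance = 1e-12)
  expect_lt(fq$q_hat["L2", "a"], sqrt(1 / (2 * 10)))
  expect_gt(fq$q_hat["L2", "a"], 0)
})

test_that("Bayesian posterior mean matches numerical quadrature", {
  set.seed(91)
  for (case in 1:20) {
    n <- sample(5:25, 1)
    m <- sample(0:n, 1)
    a <- runif(1, 0.2, 3); b <- runif(1, 0.2, 3)
    got <- landgen:::bayes_q_posterior_mean(m, n, a, b)
    dens <- function(q) dbinom(m, n, q^2) * dbeta(q, a, b)
    num <- integrate(function(q) q * dens(q), 0, 1, rel.tol = 1e-10)$value
    den <- integrate(dens, 0, 1, rel.tol = 1e-10)$value
    expect_equal(got, num / den, tolerance = 1e-6)
  }
})

test_that("Bayesian estimates shrink toward the prior mean relative to the
           square-root estimator", {
  set.seed(92)
  env <- simulate_env(n_pop = 4)
  sim <- simulate_aflp(env, n_per = 8, n_loci = 120)
  fb <- estimate_allele_frequencies(sim$markers, "bayesian")
  for (p in fb$populations) {
    # raw maximum-likelihood estimate, no boundary correction
    sub <- sim$markers$calls[sim$markers$population_of == p, ]
    q_raw <- sqrt(colMeans(sub == 0, na.rm = TRUE))
    prior_mean <- fb$prior["a", p] / sum(fb$prior[, p])
    expect_lt(mean(abs(fb$q_hat[, p] - prior_mean), na.rm = TRUE),
              mean(abs(q_raw - prior_mean), na.rm = TRUE))
  }
})

test_that("Bayesian q estimates are nearly unbiased at survey sample
           sizes", {
  set.seed(93)
  env <- simulate_env()
  bias <- numeric(5)
  for (r in 1:5) {
    sim <- simulate_aflp(env, n_loci = 300)
    fq <- estimate_allele_frequencies(sim$markers, "bayesian")
    bias[r] <- mean(fq$q_hat - (1 - sim$p_pop), na.rm = TRUE)
  }
  expect_lt(abs(mean(bias)), 0.02)
})

test_that("Nei's gene diversity is the mean per-locus heterozygosity", {
  # q = 0.5 at every locus gives the maximum 0.5
  fq <- structure(list(q_hat = matrix(0.5, 10, 1,
                                      dimnames = list(NULL, "a")),
                       populations = "a"), class = "allele_freq")
  expect_equal(nei_gene_diversity(fq)$H_E, 0.5)
  fq$q_hat[] <- 1
  expect_equal(nei_gene_diversity(fq)$H_E, 0)
  # recount oracle on simulated data
  set.seed(94)
  sim <- simulate_aflp(simulate_env(n_pop = 3), n_per = 10, n_loci = 50)
  fb <- estimate_allele_frequencies(sim$markers, "bayesian")
  nd <- nei_gene_diversity(fb)
  for (i in seq_len(3)) {
    q <- fb$q_hat[, nd$population[i]]
    expect_equal(nd$H_E[i], mean(2 * q * (1 - q), na.rm = TRUE))
  }
})

test_that("percent polymorphic applies the 5% criterion", {
  fq <- structure(list(
    q_hat = matrix(c(0.5, 0.99, 0.97, 0.03, 0.8, 0.02, 0.96, 1, 0.5, 0.6),
                   10, 1, dimnames = list(NULL, "a")),
    populations = "a"), class = "allele_freq")
  # major-allele frequency <= 0.95 for loci 1, 5, 9, 10 -> 40%
  expect_equal(percent_polymorphic(fq)$percent_polymorphic, 40)
  expect_equal(percent_polymorphic(fq, level = 0.01)$percent_polymorphic,
               90)
})

test_that("private and fixed private bands are counted per population", {
  calls <- cbind(
    L1 = c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0),  # only pop a, 3 of 5
    L2 = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),  # only pop a, all 5
    L3 = c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0))  # both pops
  mk <- toy_markers(calls, rep(c("a", "b"), each = 5))
  pb <- private_bands(mk)
  expect_equal(pb$N_p[pb$population == "a"], 2L)
  expect_equal(pb$N_fp[pb$population == "a"], 1L)
  expect_equal(pb$N_p[pb$population == "b"], 0L)
  expect_equal(pb$N_p[pb$population == "Total"], 2L)

  # brute-force oracle on simulated data
  set.seed(95)
  sim <- simulate_aflp(simulate_env(n_pop = 4), n_per = 6, n_loci = 80)
  pb2 <- private_bands(sim$markers)
  pops <- unique(sim$markers$population_of)
  pres <- sapply(pops, function(p)
    colSums(sim$markers$calls[sim$markers$population_of == p, ] == 1,
            na.rm = TRUE) > 0)
  for (p in pops) {
    manual <- sum(pres[, p] & rowSums(pres) == 1)
    expect_equal(pb2$N_p[pb2$population == p], manual)
  }
})

test_that("repeatability pools call agreement across replicate pairs", {
  a <- rep(c(0, 1), 50)
  b <- a; b[1:5] <- 1 - b[1:5]
  expect_equal(repeatability(list(rbind(a, a)))$overall, 100)
  expect_equal(repeatability(list(rbind(a, b)))$overall, 95)
  # pooled value equals the call-weighted mean of per-pair values
  r <- repeatability(list(rbind(a, b), rbind(a[1:40], a[1:40])))
  expect_equal(r$overall, (95 * 100 + 100 * 40) / 140)
  expect_error(repeatability(list(list(a, a[1:10]))), "locus set")
})

test_that("gene diversity is invariant to complementing presence and
           absence", {
  q <- c(0.2, 0.7, 0.45)
  h1 <- 2 * q * (1 - q)
  h2 <- 2 * (1 - q) * q
  expect_equal(h1, h2)
  fq1 <- structure(list(q_hat = matrix(q, 3, 1, dimnames = list(NULL, "a")),
                        populations = "a"), class = "allele_freq")
  fq2 <- structure(list(q_hat = matrix(1 - q, 3, 1,
                                       dimnames = list(NULL, "a")),
                        populations = "a"), class = "allele_freq")
  expect_equal(nei_gene_diversity(fq1)$H_E, nei_gene_diversity(fq2)$H_E)
})
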