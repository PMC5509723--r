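test_that("Tajima's D matches an independent evaluation of the 1989
           coefficients", {
  # n = 4, S = 2, k_bar = 1: evaluate a1..e2 from scratch
  n <- 4; S <- 2; k <- 1
  a1 <- sum(1 / 1:3); a2 <- sum(1 / (1:3)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  expected <- (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(tajimas_d(4, 2, 1), expected)
  expect_equal(round(tajimas_d(4, 2, 1), 3), -0.710)

  expect_equal(tajimas_d(10, 5, 5 / sum(1 / 1:9)), 0)
  expect_error(tajimas_d(10, 0, 1), "undefined")
  expect_error(tajimas_d(3, 2, 1), "n >= 4")
})

test_that("Fu's Fs follows the Ewens sampling formula", {
  # closed form at n = 2: S' = theta/(1+theta)
  expect_equal(fus_fs(2, 2, 1), 0)
  expect_equal(fus_fs(2, 2, exp(1)), 1)

  # brute-force Stirling recursion in plain integer arithmetic
  stirling <- function(n) {
    s <- matrix(0, n, n)
    s[1, 1] <- 1
    if (n > 1) for (m in 2:n) for (k in 1:m) {
      s[m, k] <- (if (k > 1) s[m - 1, k - 1] else 0) +
        (m - 1) * s[m - 1, k]
    }
    s[n, ]
  }
  ewens_exact <- function(n, theta)
    stirling(n) * theta^(1:n) / prod(theta + 0:(n - 1))
  th <- 0.8; n <- 5; k_obs <- 3
  sp <- sum(ewens_exact(n, th)[k_obs:n])
  expect_equal(fus_fs(n, k_obs, th), log(sp / (1 - sp)), tolerance = 1e-12)

  # exhaustive check of the haplotype-number pmf for n <= 8
  for (n in 2:8) for (th in c(0.3, 1, 2.7)) {
    expect_equal(ewens_haplotype_pmf(n, th), ewens_exact(n, th),
                 tolerance = 1e-10)
    expect_equal(sum(ewens_haplotype_pmf(n, th)), 1, tolerance = 1e-12)
  }
})

test_that("R2 statistic matches its defining sum", {
  expect_equal(r2_statistic(c(0, 0, 0, 2), 1, 2), sqrt(0.75) / 2)
  expect_equal(r2_statistic(rep(1, 6), 2, 3), 0)  # all U_i = k_bar/2
  expect_equal(r2_statistic(c(0, 0, 0, 2), 1, 4),
               r2_statistic(c(0, 0, 0, 2), 1, 2) / 2)  # scale in 1/S
  expect_error(r2_statistic(c(0, 1), 1, 0), "undefined|segregating")
})

test_that("neutrality statistics agree with direct computation on the
           two-site alignment", {
  ns <- neutrality_stats(two_site_alignment())
  expect_equal(ns$S, 2L)
  expect_equal(ns$k_bar, 1)
  expect_equal(ns$U, c(0, 0, 0, 2))
  expect_equal(ns$K, 2L)
  expect_equal(ns$D, tajimas_d(4, 2, 1))
  expect_equal(ns$R2, sqrt(0.75) / 2)
})

test_that("expansion spectrum reduces to its equilibrium limits and
           normalises", {
  jmax <- 30
  f0 <- expansion_spectrum(0, 0.5, 50, jmax)
  eq <- 0.5^(0:jmax) / 1.5^(1:(jmax + 1))
  expect_equal(f0, eq / sum(eq), tolerance = 1e-10)
  fbig <- expansion_spectrum(60, 0.5, 5, jmax)
  eq5 <- 5^(0:jmax) / 6^(1:(jmax + 1))
  expect_equal(fbig, eq5 / sum(eq5), tolerance = 1e-6)
  expect_equal(sum(expansion_spectrum(2, 0.5, 50, 40)), 1)
})

test_that("mismatch model fitting recovers a self-generated spectrum and
           degenerate inputs error", {
  jmax <- 25
  f <- expansion_spectrum(2, 0.5, 50, jmax)
  spec <- structure(list(counts = round(f * 1e6), freq = f, n = 50,
                         n_pairs = 1225, k_bar = sum((0:jmax) * f)),
                    class = "mismatch_spectrum")
  # the SSD at the generating parameters is identically zero; the
  # optimiser gets numerically close
  expect_equal(sum((f - expansion_spectrum(2, 0.5, 50, jmax))^2), 0)
  fit <- fit_mismatch_expansion(spec)
  expect_lt(fit$SSD, 1e-4)
  expect_equal(fit$tau, 2, tolerance = 0.15)

  # flat spectrum has zero raggedness
  flat <- structure(list(counts = rep(25L, 4), freq = rep(0.25, 4), n = 10,
                         n_pairs = 100, k_bar = 1.5),
                    class = "mismatch_spectrum")
  expect_equal(fit_mismatch_expansion(flat)$raggedness, 0)

  single <- structure(list(counts = c(`0` = 10L), freq = c(`0` = 1), n = 5,
                           n_pairs = 10, k_bar = 0),
                      class = "mismatch_spectrum")
  expect_error(fit_mismatch_expansion(single), "degenerate")
})

test_that("KS mismatch distance equals a brute-force ECDF scan", {
  set.seed(41)
  sim <- simulate_coalescent_alignment(20, 6, sites = 400)
  sp <- mismatch_spectrum(sim)
  fit <- fit_mismatch_expansion(sp)
  ks <- mismatch_ks_test(sp, fit)
  brute <- max(abs(cumsum(sp$freq) - cumsum(fit$expected)))
  expect_equal(ks$statistic, brute)
  # observed equal to expected gives distance zero
  sp2 <- sp; sp2$freq <- fit$expected
  sp2$counts <- round(fit$expected * sp$n_pairs)
  expect_equal(mismatch_ks_test(sp2, fit)$statistic, 0)
  # bootstrap p is a valid probability
  ksp <- mismatch_ks_test(sp, fit, boot = 19)
  expect_gte(ksp$p, 0); expect_lte(ksp$p, 1)
})

test_that("expansion dating implements t = tau/(2*mu*k) with CI mapping", {
  d <- date_expansion(1.6167, 1.5e-8, 2, 1264,
                      tau_ci = c(0.30225, 8.57544))
  expect_equal(d$t_generations, 1.6167 / (2 * 3e-8 * 1264))
  expect_equal(round(d$t_generations), 21317)
  expect_equal(round(d$t_generations_ci), c(3985, 113073))
  expect_equal(d$t_years, d$t_generations * 2)
  expect_equal(date_expansion(0, 1e-8, 2, 100)$t_generations, 0)
  # linear in tau, inverse-linear in mu and k
  set.seed(5)
  for (i in 1:5) {
    tau <- runif(1, 0.1, 5); mu <- runif(1, 1e-9, 1e-7)
    g <- runif(1, 1, 10); k <- sample(500:2000, 1)
    t0 <- date_expansion(tau, mu, g, k)$t_generations
    expect_equal(date_expansion(2 * tau, mu, g, k)$t_generations, 2 * t0)
    expect_equal(date_expansion(tau, 2 * mu, g, k)$t_generations, t0 / 2)
    expect_equal(date_expansion(tau, mu, g, 2 * k)$t_generations, t0 / 2)
  }
})

test_that("coalescent p-values centre observed-median statistics near 0.5
           and insist on enough replicates", {
  set.seed(51)
  null <- coalescent_null(15, S = 8, replicates = 400)
  med <- median(null$D, na.rm = TRUE)
  obs <- list(n = 15, S = 8, D = med, Fs = median(null$Fs, na.rm = TRUE),
              R2 = median(null$R2, na.rm = TRUE))
  np <- neutrality_pvalues(obs, null = null)
  expect_equal(np$p_D, 0.5, tolerance = 0.08)
  expect_equal(np$p_Fs, 0.5, tolerance = 0.08)
  expect_equal(np$p_R2, 0.5, tolerance = 0.08)
  expect_error(neutrality_pvalues(obs, replicates = 50), "100")
})

test_that("strongly negative D from an expansion sample rejects the
           constant-size null", {
  set.seed(61)
  rejected <- 0
  for (r in 1:10) {
    st <- landgen:::sim_replicate_stats(50, theta = 50,
                                        demography = "sudden-expansion",
                                        t_expansion = 2 / 50,
                                        growth_factor = 100)
    if (st$S < 1) next
    obs <- list(n = 50, S = st$S, k_bar = st$k_bar,
                D = tajimas_d(50, st$S, st$k_bar),
                Fs = fus_fs(50, st$K, st$k_bar),
                R2 = r2_statistic(st$U, st$k_bar, st$S))
    np <- neutrality_pvalues(obs, replicates = 200)
    if (np$p_D < 0.05) rejected <- rejected + 1
  }
  expect_gte(rejected, 8)
})
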