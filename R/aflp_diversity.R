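# Dominant-marker allele-frequency estimation and within-population
# diversity. Band absence is the recessive homozygote under Hardy-Weinberg,
# so the null-allele frequency q satisfies q^2 = P(no band).

# log posterior-mean of q under Beta(a,b) prior and m absent of n:
# posterior density propto q^(2m+a-1) (1-q)^(n-m+b-1) (1+q)^(n-m)
# Expanding (1+q)^(n-m) binomially gives sums of Beta functions.
bayes_q_posterior_mean <- function(m, n, a, b) {
  if (n == 0L) return(NA_real_)
  r <- n - m
  j <- 0:r
  lw <- lchoose(r, j) + lbeta(2 * m + a + j, r + b)
  lw1 <- lchoose(r, j) + lbeta(2 * m + a + j + 1, r + b)
  mx <- max(lw)
  exp(log(sum(exp(lw1 - mx))) - log(sum(exp(lw - mx))))
}

# method-of-moments Beta(a,b) fit to a vector of frequency estimates
fit_beta_moments <- function(q) {
  q <- q[is.finite(q)]
  m <- mean(q)
  v <- stats::var(q)
  vmax <- m * (1 - m)
  if (!is.finite(v) || v <= 0 || v >= vmax)
    v <- vmax / 2
  k <- vmax / v - 1
  c(a = max(m * k, 0.05), b = max((1 - m) * k, 0.05))
}

#' Estimate null-allele frequencies from dominant marker data
#'
#' Per locus and population, estimates the frequency `q` of the band-absent
#' (recessive) allele from the fraction of individuals without the band,
#' assuming Hardy-Weinberg proportions within populations. Two estimators:
#'
#' * `"bayesian"` (default): posterior mean of q under a non-uniform
#'   Beta(a,b) prior whose parameters are fitted per population by the
#'   method of moments to the across-locus distribution of square-root
#'   estimates (Zhivotovsky-style, as used for AFLP data).
#' * `"sqrt"`: `q = sqrt(absence fraction)`, with a zero-class correction
#'   replacing an absence fraction of 0 by `1/(2(n+1))` so fully banded
#'   loci get a small positive q rather than 0.
#'
#' Missing calls are excluded locus-wise per population.
#'
#' @param markers a [marker_matrix()].
#' @param method `"bayesian"` or `"sqrt"`.
#' @return Object of class `allele_freq`: list with `q_hat` and
#'   `band_freq` (locus x population matrices), `n_scored` (same shape),
#'   `prior` (per-population Beta parameters, bayesian only), `method`,
#'   `populations`, `locus_ids`.
#' @export
estimate_allele_frequencies <- function(markers,
                                        method = c("bayesian", "sqrt")) {
  stopifnot(inherits(markers, "marker_matrix"))
  method <- match.arg(method)
  pops <- unique(markers$population_of)
  L <- ncol(markers$calls)
  q_hat <- band <- nsc <- matrix(
    NA_real_, L, length(pops),
    dimnames = list(markers$locus_ids, pops))
  prior <- matrix(NA_real_, 2L, length(pops),
                  dimnames = list(c("a", "b"), pops))
  for (p in pops) {
    sub <- markers$calls[markers$population_of == p, , drop = FALSE]
    n <- colSums(!is.na(sub))
    absent <- colSums(sub == 0, na.rm = TRUE)
    nsc[, p] <- n
    band[, p] <- ifelse(n > 0, 1 - absent / n, NA_real_)
    frac <- ifelse(n > 0, absent / n, NA_real_)
    zero <- !is.na(frac) & frac == 0
    frac[zero] <- 1 / (2 * (n[zero] + 1))
    q_sqrt <- sqrt(frac)
    if (method == "sqrt") {
      q_hat[, p] <- q_sqrt
    } else {
      ab <- fit_beta_moments(q_sqrt)
      prior[, p] <- ab
      q_hat[, p] <- vapply(seq_len(L), function(l) {
        if (n[l] == 0L) return(NA_real_)
        bayes_q_posterior_mean(absent[l], n[l], ab["a"], ab["b"])
      }, numeric(1L))
    }
  }
  structure(
    list(q_hat = q_hat, band_freq = band, n_scored = nsc,
         prior = if (method == "bayesian") prior else NULL,
         method = method, populations = pops,
         locus_ids = markers$locus_ids),
    class = "allele_freq")
}

#' @export
print.allele_freq <- function(x, ...) {
  cat("Null-allele frequency estimates (", x$method, ") for ",
      nrow(x$q_hat), " loci x ", length(x$populations), " populations\n",
      sep = "")
  invisible(x)
}

#' Nei's gene diversity per population
#'
#' Per-locus expected heterozygosity `h = 1 - p^2 - q^2 = 2pq` from the
#' estimated allele frequencies; the population value `H_E` is the mean over
#' loci, with its standard error over loci.
#'
#' @param freqs an [estimate_allele_frequencies()] result.
#' @return Data frame with one row per population: `population`, `H_E`,
#'   `SE`, `n_loci`.
#' @export
nei_gene_diversity <- function(freqs) {
  stopifnot(inherits(freqs, "allele_freq"))
  out <- lapply(freqs$populations, function(p) {
    q <- freqs$q_hat[, p]
    q <- q[!is.na(q)]
    h <- 2 * (1 - q) * q
    data.frame(population = p, H_E = mean(h),
               SE = stats::sd(h) / sqrt(length(h)),
               n_loci = length(h))
  })
  do.call(rbind, out)
}

#' Percentage of polymorphic loci
#'
#' A locus counts as polymorphic in a population when its more common
#' allele's estimated frequency is at most `1 - level` (the conventional
#' "5% level" uses `level = 0.05`).
#'
#' @param freqs an [estimate_allele_frequencies()] result.
#' @param level polymorphism level (default 0.05).
#' @return Data frame: `population`, `percent_polymorphic`, `n_loci`.
#' @export
percent_polymorphic <- function(freqs, level = 0.05) {
  stopifnot(inherits(freqs, "allele_freq"))
  out <- lapply(freqs$populations, function(p) {
    q <- freqs$q_hat[, p]
    q <- q[!is.na(q)]
    major <- pmax(q, 1 - q)
    data.frame(population = p,
               percent_polymorphic = 100 * mean(major <= 1 - level),
               n_loci = length(q))
  })
  do.call(rbind, out)
}

#' Private and fixed private bands per population
#'
#' `N_p` counts loci whose band occurs in exactly one population; `N_fp`
#' counts those among them whose band is carried by every scored individual
#' of that population.
#'
#' @param markers a [marker_matrix()] with at least two populations.
#' @return Data frame: `population`, `N_p`, `N_fp`, plus a `Total` row
#'   (column sums).
#' @export
private_bands <- function(markers) {
  stopifnot(inherits(markers, "marker_matrix"))
  pops <- unique(markers$population_of)
  if (length(pops) < 2L)
    stop("private bands require at least two populations", call. = FALSE)
  pres <- sapply(pops, function(p) {
    sub <- markers$calls[markers$population_of == p, , drop = FALSE]
    colSums(sub == 1, na.rm = TRUE) > 0
  })
  fixed <- sapply(pops, function(p) {
    sub <- markers$calls[markers$population_of == p, , drop = FALSE]
    n <- colSums(!is.na(sub))
    n > 0 & colSums(sub == 1, na.rm = TRUE) == n
  })
  npops_with_band <- rowSums(pres)
  out <- lapply(pops, function(p) {
    priv <- pres[, p] & npops_with_band == 1L
    data.frame(population = p, N_p = sum(priv),
               N_fp = sum(priv & fixed[, p]))
  })
  out <- do.call(rbind, out)
  rbind(out, data.frame(population = "Total", N_p = sum(out$N_p),
                        N_fp = sum(out$N_fp)))
}

#' Genotyping repeatability from replicate band profiles
#'
#' Fraction of locus calls identical across replicate pairs, pooled over all
#' pairs and loci (equivalently the call-weighted mean of per-pair values).
#'
#' @param pairs list of two-row matrices (or list(a, b) vectors) of 0/1
#'   calls over the same loci; each element is one replicate pair.
#' @return List with `overall` (percent), `per_pair` (percent per pair).
#' @export
repeatability <- function(pairs) {
  stopifnot(length(pairs) >= 1L)
  agree <- tot <- numeric(length(pairs))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    if (is.matrix(pr)) { a <- pr[1L, ]; b <- pr[2L, ] }
    else { a <- pr[[1L]]; b <- pr[[2L]] }
    if (length(a) != length(b))
      stop("replicate profiles differ in locus set", call. = FALSE)
    ok <- !is.na(a) & !is.na(b)
    agree[i] <- sum(a[ok] == b[ok])
    tot[i] <- sum(ok)
  }
  list(overall = 100 * sum(agree) / sum(tot),
       per_pair = 100 * agree / tot)
}
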