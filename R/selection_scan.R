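# FST-outlier scanning against a simulated neutral envelope.
#
# The neutral model is a Balding-Nichols island model: per-population
# band-allele frequencies are Beta(pbar*(1-F)/F, (1-pbar)*(1-F)/F) around an
# ancestral frequency pbar, dominant phenotypes are Binomial draws of band
# presence 1-(1-p)^2, and the same frequency-estimation and Weir-Cockerham
# chain as for the observed data is applied. This matches the first two
# moments the envelope conditions on (heterozygosity, FST) while staying
# desk-scale fast; it is a deliberate simplification of a coalescent island
# model.

# simulate nloci neutral dominant loci under Balding-Nichols F, given
# per-population sample sizes nvec and ancestral band-allele frequencies
# pbar (vector recycled to nloci). Returns absence fractions and sizes so
# the exact estimator chain applied to observed data can be re-applied.
sim_neutral_loci <- function(nloci, nvec, F, pbar) {
  P <- length(nvec)
  pbar <- rep_len(pbar, nloci)
  shape_scale <- (1 - F) / F
  pmat <- matrix(stats::rbeta(nloci * P,
                              rep(pbar, P) * shape_scale,
                              rep(1 - pbar, P) * shape_scale),
                 nloci, P)
  nmat <- matrix(rep(nvec, each = nloci), nloci, P)
  # dominant phenotype counts: band shown with prob 1-(1-p)^2
  shown <- matrix(stats::rbinom(nloci * P, nmat, 1 - (1 - pmat)^2),
                  nloci, P)
  list(x = 1 - shown / nmat, n = nmat)
}

# per-locus FST and mean heterozygosity from absence fractions + sizes;
# heterozygosity is 2*p*q of the square-root frequency estimate
locus_fst_het <- function(x, nmat) {
  fst <- wc_theta_dominant_per_locus(x, nmat)
  q <- sqrt(x)
  het <- rowMeans(2 * (1 - q) * q, na.rm = TRUE)
  list(fst = fst, het = het)
}

# trimmed mean FST: drop the top and bottom `trim` fraction of loci
trimmed_mean_fst <- function(fst, trim = 0.3) {
  fst <- sort(fst[is.finite(fst)])
  L <- length(fst)
  lo <- floor(L * trim) + 1L
  hi <- L - floor(L * trim)
  mean(fst[lo:hi])
}

# assign values to equal-width bins over [lo, hi], merging sparse bins
# (fewer than min_per simulated entries) with their left neighbour
make_het_bins <- function(het_sim, n_bins = 20L, min_per = 30L) {
  rng <- range(het_sim, finite = TRUE)
  if (diff(rng) == 0) rng <- rng + c(-1e-6, 1e-6)
  br <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  br[1L] <- -Inf; br[length(br)] <- Inf
  cnt <- tabulate(findInterval(het_sim, br, rightmost.closed = TRUE),
                  nbins = n_bins)
  keep <- rep(TRUE, length(br))
  i <- 2L
  while (i <= n_bins) {
    if (cnt[i - 1L] < min_per && sum(keep) > 2L) {
      # merge bin i-1 into its neighbour by dropping the boundary
      keep[i] <- FALSE
      cnt[i] <- cnt[i] + cnt[i - 1L]
      cnt[i - 1L] <- 0L
    }
    i <- i + 1L
  }
  br[keep]
}

#' FDIST-style FST outlier scan
#'
#' Identifies loci with unusually high FST relative to a simulated neutral
#' envelope conditioned on heterozygosity:
#'
#' 1. observed per-locus Weir-Cockerham FST and mean within-population
#'    heterozygosity are computed from estimated band-allele frequencies;
#' 2. a trimmed mean FST is taken after discarding the highest and lowest
#'    30% of per-locus values;
#' 3. neutral loci are simulated under a Balding-Nichols island model whose
#'    F parameter is calibrated iteratively (at reduced size) until the
#'    simulated trimmed mean FST is within `calib_tol` of the observed one;
#' 4. each locus gets an empirical p-value: the (+1-corrected) fraction of
#'    simulated loci in the same heterozygosity bin with FST at least as
#'    large;
#' 5. outliers are loci above the 95% conditional quantile (p < 0.05) that
#'    also survive Benjamini-Hochberg control at FDR 5% — the two filters
#'    are applied conjunctively.
#'
#' @param markers a [marker_matrix()].
#' @param n_sim simulated neutral loci for the final envelope.
#' @param estimator allele-frequency estimator applied identically to
#'   observed and simulated data (`"sqrt"` default: the envelope chain is
#'   self-consistent and fast).
#' @param alpha conditional quantile level (default 0.05).
#' @param fdr Benjamini-Hochberg false-discovery rate (default 0.05).
#' @param n_bins heterozygosity bins (sparse bins are merged below 30
#'   simulated loci).
#' @param calib_tol calibration tolerance on the trimmed mean FST.
#' @param calib_sim simulated loci per calibration iteration.
#' @return Object of class `locus_scan`: data frame (`locus`, `fst`, `het`,
#'   `p`, `q`, `outlier`) plus attributes `envelope` (simulated fst/het),
#'   `F_calibrated`, `trimmed_mean_fst`, `excluded` (monomorphic loci,
#'   never flagged).
#' @export
fdist_scan <- function(markers, n_sim = 3e5, estimator = "sqrt",
                       alpha = 0.05, fdr = 0.05, n_bins = 20L,
                       calib_tol = 0.005, calib_sim = 2e4) {
  stopifnot(inherits(markers, "marker_matrix"))
  freqs <- estimate_allele_frequencies(markers, method = estimator)
  pops <- freqs$populations
  if (length(pops) < 2L) stop("need >= 2 populations", call. = FALSE)
  xmat <- 1 - freqs$band_freq  # absence fractions
  nmat <- freqs$n_scored
  band <- freqs$band_freq
  poly <- apply(band, 1L, function(b) {
    b <- b[!is.na(b)]
    length(b) > 0L && any(b > 0) && any(b < 1)
  })
  if (sum(poly) < 50L)
    warning("fewer than 50 polymorphic loci: neutral envelope is unstable")
  obs <- locus_fst_het(xmat[poly, , drop = FALSE],
                       nmat[poly, , drop = FALSE])
  target <- trimmed_mean_fst(obs$fst)
  target <- max(target, 1e-3)
  nvec <- round(colMeans(nmat, na.rm = TRUE))
  # ancestral band-allele frequencies resampled from the observed pooled
  # band-frequency estimates (jittered), so the envelope spans the observed
  # heterozygosity range
  pbar_pool <- 1 - sqrt(rowMeans(xmat[poly, , drop = FALSE], na.rm = TRUE))
  draw_pbar <- function(k) {
    pb <- sample(pbar_pool, k, replace = TRUE) +
      stats::rnorm(k, 0, 0.02)
    pmin(pmax(pb, 0.01), 0.99)
  }
  # calibrate F at reduced simulation size
  F_cur <- min(max(target, 0.01), 0.9)
  for (it in seq_len(20L)) {
    sim <- sim_neutral_loci(calib_sim, nvec, F_cur, draw_pbar(calib_sim))
    st <- locus_fst_het(sim$x, sim$n)
    cur <- trimmed_mean_fst(st$fst)
    if (is.finite(cur) && abs(cur - target) <= calib_tol) break
    F_cur <- min(max(F_cur * target / max(cur, 1e-4), 1e-3), 0.95)
  }
  sim <- sim_neutral_loci(n_sim, nvec, F_cur, draw_pbar(n_sim))
  env <- locus_fst_het(sim$x, sim$n)
  br <- make_het_bins(env$het, n_bins = n_bins)
  bin_sim <- findInterval(env$het, br, rightmost.closed = TRUE)
  bin_obs <- findInterval(obs$het, br, rightmost.closed = TRUE)
  pvals <- rep(NA_real_, length(obs$fst))
  for (b in unique(bin_obs)) {
    inb <- bin_sim == b
    if (!any(inb)) inb <- rep(TRUE, length(bin_sim))  # widen to all
    sf <- env$fst[inb]
    sf <- sf[is.finite(sf)]
    idx <- which(bin_obs == b)
    ge <- vapply(obs$fst[idx], function(f) sum(sf >= f), numeric(1L))
    pvals[idx] <- (1 + ge) / (1 + length(sf))
  }
  qvals <- stats::p.adjust(pvals, method = "BH")
  out <- data.frame(
    locus = freqs$locus_ids[poly],
    fst = obs$fst, het = obs$het, p = pvals, q = qvals,
    outlier = pvals < alpha & qvals <= fdr)
  structure(out, class = c("locus_scan", "data.frame"),
            envelope = data.frame(fst = env$fst, het = env$het),
            F_calibrated = F_cur,
            trimmed_mean_fst = target,
            alpha = alpha, fdr = fdr,
            excluded = freqs$locus_ids[!poly])
}

#' @export
print.locus_scan <- function(x, ...) {
  cat(sprintf(
    "FST outlier scan: %d loci (%d monomorphic excluded), F calibrated to %.4f\n",
    nrow(x), length(attr(x, "excluded")), attr(x, "F_calibrated")))
  n_out <- sum(x$outlier, na.rm = TRUE)
  cat(n_out, "outliers at the", 100 * (1 - attr(x, "alpha")),
      "% conditional quantile with FDR", attr(x, "fdr"), "\n")
  if (n_out > 0)
    print(as.data.frame(x)[which(x$outlier), ], row.names = FALSE)
  invisible(x)
}

#' Combine outlier flags and environmental associations into adaptive-locus
#' calls
#'
#' A locus is called adaptive when it was flagged by at least one of the two
#' outlier-scan methods AND shows at least one significant environmental
#' association. The rule is monotone: adding a flag can only grow the
#' adaptive set.
#'
#' @param fdist_flags named logical vector (or `locus_scan`) of
#'   envelope-scan outlier flags.
#' @param bayes_flags named logical vector (or `bayescan_result`) of
#'   posterior-odds outlier flags.
#' @param assoc an `association_table` (or data frame with columns `locus`,
#'   `variable`, `significant`).
#' @return Object of class `adaptive_calls`: data frame with one row per
#'   locus (`locus`, `fdist`, `bayes`, `n_assoc`, `variables`, `adaptive`).
#' @export
call_adaptive_loci <- function(fdist_flags, bayes_flags, assoc) {
  full_objects <- inherits(fdist_flags, "locus_scan") &&
    inherits(bayes_flags, "bayescan_result")
  if (inherits(fdist_flags, "locus_scan"))
    fdist_flags <- stats::setNames(fdist_flags$outlier, fdist_flags$locus)
  if (inherits(bayes_flags, "bayescan_result"))
    bayes_flags <- stats::setNames(bayes_flags$outlier, bayes_flags$locus)
  assoc <- as.data.frame(assoc)
  loci <- sort(union(union(names(fdist_flags), names(bayes_flags)),
                     unique(assoc$locus)))
  if (full_objects &&
      !setequal(names(fdist_flags), names(bayes_flags)))
    stop("locus-set mismatch between the two outlier scans", call. = FALSE)
  fd <- stats::setNames(rep(FALSE, length(loci)), loci)
  fd[names(fdist_flags)] <- fdist_flags %in% TRUE
  bs <- stats::setNames(rep(FALSE, length(loci)), loci)
  bs[names(bayes_flags)] <- bayes_flags %in% TRUE
  sig <- assoc[assoc$significant %in% TRUE, , drop = FALSE]
  n_assoc <- stats::setNames(rep(0L, length(loci)), loci)
  vars <- stats::setNames(rep("", length(loci)), loci)
  if (nrow(sig)) {
    tb <- table(factor(sig$locus, levels = loci))
    n_assoc[] <- as.integer(tb)
    agg <- tapply(sig$variable, factor(sig$locus, levels = loci),
                  function(v) paste(sort(unique(v)), collapse = ","))
    vars[!is.na(agg)] <- agg[!is.na(agg)]
  }
  out <- data.frame(
    locus = loci, fdist = unname(fd), bayes = unname(bs),
    n_assoc = unname(n_assoc), variables = unname(vars),
    adaptive = unname((fd | bs) & n_assoc >= 1L))
  structure(out, class = c("adaptive_calls", "data.frame"))
}

#' @export
print.adaptive_calls <- function(x, ...) {
  ad <- x$locus[x$adaptive]
  cat("Adaptive loci (outlier AND associated):",
      if (length(ad)) paste(ad, collapse = ", ") else "none", "\n")
  invisible(x)
}
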