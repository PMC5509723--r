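# Variance-components FST estimation for dominant markers.
#
# The square-root estimator q_hat = sqrt(absence fraction) is a nonlinear
# transform of a binomial observation, so its bias and variance depend on q
# and on the per-population sample size. A naive Weir-Cockerham analysis of
# these estimates is badly biased at AFLP sample sizes. Instead we work on
# the observation scale: sqrt(x) has expectation h(q) = E[sqrt(X/n)] under
# X ~ Bin(n, q^2), computable exactly. Per locus, a pooled reference
# frequency q0 = h^{-1}(mean sqrt(x)) anchors the corrections; the
# between-population variance component is the sampling-variance-corrected
# spread of sqrt(x), rescaled by h'(q0)^2 back to the frequency scale; the
# denominator is the total-variance term q0(1-q0) + sigma2_B/r. Multi-locus
# aggregation is ratio-of-sums, the standard variance-components practice.

# exact moments of sqrt(X/n), X ~ Bin(n, q^2), tabulated over q per n
dominant_moment_tables <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    qg <- seq(0, 1, length.out = 2001L)
    h <- vapply(qg^2, function(t)
      sum(sqrt((0:n) / n) * stats::dbinom(0:n, n, t)), numeric(1L))
    v <- pmax(qg^2 - h^2, 0)
    tab <- list(
      h = stats::approxfun(qg, h),
      g = stats::approxfun(h, qg, rule = 2L),        # inverse of h
      hprime = stats::approxfun(qg, c(diff(h) / diff(qg),
                                      (h[2001L] - h[2000L]) /
                                        (qg[2001L] - qg[2000L]))),
      v = stats::approxfun(qg, v))
    cache[[key]] <- tab
    tab
  }
})

# per-locus numerator (between-population variance component) and
# denominator (total variance) from absence fractions x (loci x pops) and
# scored sample sizes nmat. Returns list(sB, D); NA rows where degenerate.
# Vectorised over loci, grouped by the per-locus mean sample size that
# selects the exact-moment table.
fst_dominant_components <- function(x, nmat) {
  x <- as.matrix(x); nmat <- as.matrix(nmat)
  L <- nrow(x)
  sB <- D <- rep(NA_real_, L)
  bad <- is.na(x) | nmat <= 0
  r_eff <- rowSums(!bad)
  nl <- pmax(2L, as.integer(round(rowSums(nmat * !bad) / pmax(r_eff, 1L))))
  for (nv in unique(nl[r_eff >= 2L])) {
    idx <- which(nl == nv & r_eff >= 2L)
    tab <- dominant_moment_tables(nv)
    sq <- sqrt(x[idx, , drop = FALSE])
    sq[bad[idx, , drop = FALSE]] <- NA
    m1 <- rowMeans(sq, na.rm = TRUE)
    r <- r_eff[idx]
    s2 <- (rowSums(sq^2, na.rm = TRUE) - r * m1^2) / (r - 1)
    q0 <- tab$g(m1)
    hp <- tab$hprime(q0)
    qj <- matrix(tab$g(as.vector(sq)), nrow = length(idx))
    vbar <- rowMeans(matrix(tab$v(as.vector(qj)), nrow = length(idx)),
                     na.rm = TRUE)
    sb <- (s2 - vbar) / hp^2
    dd <- q0 * (1 - q0) + sb / r
    ok <- is.finite(q0) & q0 > 0.001 & q0 < 0.999 &
      is.finite(sb) & is.finite(dd) & dd > 0
    sB[idx[ok]] <- sb[ok]
    D[idx[ok]] <- dd[ok]
  }
  list(sB = sB, D = D)
}

# multi-locus dominant-marker FST, ratio of sums over loci
wc_theta_dominant <- function(x, nmat) {
  comp <- fst_dominant_components(x, nmat)
  ok <- is.finite(comp$sB) & is.finite(comp$D)
  if (!any(ok)) return(0)
  sum(comp$sB[ok]) / sum(comp$D[ok])
}

# per-locus dominant-marker FST
wc_theta_dominant_per_locus <- function(x, nmat) {
  comp <- fst_dominant_components(x, nmat)
  comp$sB / comp$D
}

# codominant-frequency Weir-Cockerham components, used when per-population
# allele frequencies are observed directly (e.g. simulation truths)
wc_components <- function(p, n, h = 2 * p * (1 - p)) {
  ok <- !is.na(p) & n > 0
  p <- p[ok]; n <- n[ok]; h <- h[ok]
  r <- length(p)
  if (r < 2L) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# multi-locus Weir-Cockerham theta on observed frequencies, ratio of sums
wc_theta <- function(pmat, nmat) {
  comp <- vapply(seq_len(nrow(pmat)), function(l)
    wc_components(pmat[l, ], nmat[l, ]), numeric(3L))
  num <- sum(comp[1L, ], na.rm = TRUE)
  den <- sum(colSums(comp, na.rm = TRUE))
  if (den == 0) return(0)
  num / den
}

#' Pairwise FST between populations from dominant-marker data
#'
#' Variance-components (Weir-Cockerham-type) estimator for dominant
#' markers, aggregated over loci by ratio of sums. Because the band-absence
#' fraction estimates the squared null-allele frequency, the components are
#' computed on the square-root observation scale with exact binomial
#' corrections for its sampling bias and variance (see
#' the package vignette); a naive analysis of the point estimates is
#' substantially biased at typical AFLP sample sizes. Negative estimates
#' are retained as computed and flagged.
#'
#' @param freqs an [estimate_allele_frequencies()] result (the estimator
#'   uses the raw band frequencies and sample sizes it carries).
#' @return Object of class `fst_matrix`: symmetric matrix with zero
#'   diagonal, attribute `source = "dominant"` and attribute `negatives`
#'   listing flagged pairs.
#' @export
pairwise_fst_dominant <- function(freqs) {
  stopifnot(inherits(freqs, "allele_freq"))
  pops <- freqs$populations
  if (length(pops) < 2L) stop("need >= 2 populations", call. = FALSE)
  x <- 1 - freqs$band_freq  # band-absence fraction, estimates q^2
  nm <- freqs$n_scored
  P <- length(pops)
  m <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1L)) for (j in seq.int(i + 1L, P)) {
    m[i, j] <- m[j, i] <- wc_theta_dominant(x[, c(i, j), drop = FALSE],
                                            nm[, c(i, j), drop = FALSE])
  }
  neg <- which(m < 0 & upper.tri(m), arr.ind = TRUE)
  structure(m, class = c("fst_matrix", "matrix"),
            source = "dominant",
            negatives = if (nrow(neg))
              paste(pops[neg[, 1L]], pops[neg[, 2L]], sep = "-"))
}

#' Pairwise Phi-ST between populations from sequence data
#'
#' Distance-based fixation index computed from pairwise nucleotide
#' differences (the AMOVA Phi-ST applied to each population pair).
#'
#' @param aln an [aligned_sequence_set()].
#' @param policy site-filter policy.
#' @return An `fst_matrix` with attribute `source = "sequence"`.
#' @export
pairwise_phist_sequence <- function(aln, policy = "exclude-gap-columns") {
  stopifnot(inherits(aln, "aln_set"))
  fs <- filter_sites(aln, policy)
  d2 <- pairwise_diffs(fs$matrix, policy)  # differences as distances
  pops <- unique(aln$population_of)
  P <- length(pops)
  if (P < 2L) stop("need >= 2 populations", call. = FALSE)
  m <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1L)) for (j in seq.int(i + 1L, P)) {
    sel <- aln$population_of %in% pops[c(i, j)]
    am <- amova_from_distance(d2[sel, sel, drop = FALSE],
                              aln$population_of[sel], n_permutations = 0L)
    m[i, j] <- m[j, i] <- am$phi_st
  }
  structure(m, class = c("fst_matrix", "matrix"), source = "sequence",
            negatives = NULL)
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("Pairwise FST (", attr(x, "source"), " markers)\n", sep = "")
  print(round(unclass(x), 4))
  if (!is.null(attr(x, "negatives")))
    cat("Negative (retained, flagged):",
        paste(attr(x, "negatives"), collapse = ", "), "\n")
  invisible(x)
}

#' Mean pairwise FST of each population against the rest
#'
#' Row means of the pairwise FST matrix excluding the diagonal. The
#' highest-scoring population is flagged as the candidate glacial refugium
#' (long-isolated populations accumulate divergence from all others); ties
#' are flagged rather than broken.
#'
#' @param m an `fst_matrix` with at least 3 populations.
#' @return Object of class `refugium_score`: data frame `population`,
#'   `mean_fst`, `rank`; attributes `candidate` and `tie`.
#' @export
mean_population_fst <- function(m) {
  stopifnot(inherits(m, "fst_matrix"))
  if (nrow(m) < 3L) stop("need >= 3 populations", call. = FALSE)
  um <- unclass(m)
  diag(um) <- NA
  sc <- rowMeans(um, na.rm = TRUE)
  out <- data.frame(population = rownames(m), mean_fst = sc,
                    rank = rank(-sc, ties.method = "min"))
  rownames(out) <- NULL
  top <- out$population[out$rank == 1L]
  structure(out, class = c("refugium_score", "data.frame"),
            candidate = if (length(top) == 1L) top else NA_character_,
            tie = length(top) > 1L)
}

# AMOVA from a squared-distance matrix (here: pairwise difference counts or
# squared Euclidean band distances) and population labels.
amova_from_distance <- function(d2, pop, n_permutations = 999L) {
  N <- nrow(d2)
  pop <- as.character(pop)
  pops <- unique(pop)
  P <- length(pops)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within_of <- function(pp) {
    s <- 0
    for (g in unique(pp)) {
      idx <- which(pp == g)
      if (length(idx) > 1L)
        s <- s + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    s
  }
  phi_of <- function(pp) {
    ssw <- ss_within_of(pp)
    ssa <- ss_total - ssw
    df_a <- P - 1L
    df_w <- N - P
    ms_a <- ssa / df_a
    ms_w <- ssw / df_w
    np <- table(pp)
    n_prime <- (N - sum(np^2) / N) / df_a
    s2_w <- ms_w
    s2_a <- (ms_a - ms_w) / n_prime
    tot <- s2_a + s2_w
    list(phi = if (tot > 0) s2_a / tot else 0,
         s2_a = s2_a, s2_w = s2_w,
         ss = c(among = ssa, within = ssw),
         df = c(among = df_a, within = df_w))
  }
  obs <- phi_of(pop)
  p <- NA_real_
  if (n_permutations > 0L) {
    perm <- replicate(n_permutations, phi_of(sample(pop))$phi)
    p <- (1 + sum(perm >= obs$phi)) / (1 + n_permutations)
  }
  structure(
    list(phi_st = obs$phi, sigma2_among = obs$s2_a,
         sigma2_within = obs$s2_w, ss = obs$ss, df = obs$df,
         p = p, permutations = n_permutations),
    class = "amova_result")
}

#' AMOVA Phi-ST for dominant markers or sequences
#'
#' One-level analysis of molecular variance. For marker matrices, distances
#' are squared Euclidean distances between 0/1 band profiles (missing calls
#' mean-imputed per locus); for alignments, pairwise nucleotide differences.
#' Significance is the fraction of label permutations with Phi-ST at least
#' the observed value, with +1 correction.
#'
#' @param x a [marker_matrix()] or [aligned_sequence_set()].
#' @param n_permutations permutation count (>= 10; 0 skips the test).
#' @param groups optional alternative grouping vector (e.g. DAPC clusters),
#'   named by individual, replacing the population labels.
#' @return Object of class `amova_result`: `phi_st`, variance components,
#'   sums of squares, `p`, `permutations`.
#' @export
amova_phist <- function(x, n_permutations = 999L, groups = NULL) {
  if (n_permutations != 0L && n_permutations < 10L)
    stop("fewer than 10 permutations is refused", call. = FALSE)
  if (inherits(x, "marker_matrix")) {
    m <- x$calls
    for (j in seq_len(ncol(m))) {
      mis <- is.na(m[, j])
      if (any(mis)) m[mis, j] <- mean(m[, j], na.rm = TRUE)
    }
    d2 <- as.matrix(stats::dist(m))^2
    pop <- x$population_of
  } else if (inherits(x, "aln_set")) {
    fs <- filter_sites(x)
    d2 <- pairwise_diffs(fs$matrix)
    dimnames(d2) <- list(x$sample_ids, x$sample_ids)
    pop <- x$population_of
  } else stop("unsupported input", call. = FALSE)
  if (!is.null(groups)) pop <- groups[rownames(d2)]
  tb <- table(pop)
  if (length(tb) < 2L || any(tb < 2L))
    stop("AMOVA needs >= 2 populations with >= 2 individuals each",
         call. = FALSE)
  amova_from_distance(d2, pop, n_permutations)
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA: Phi_ST = %.4f (P = %s, %d permutations)\n",
              x$phi_st, format(x$p, digits = 3), x$permutations))
  cat(sprintf("  sigma2 among = %.4f, sigma2 within = %.4f\n",
              x$sigma2_among, x$sigma2_within))
  invisible(x)
}

#' K-means clustering on principal components with BIC model choice
#'
#' First step of a DAPC-style analysis: PCA on the centred band matrix,
#' retaining the components that cover at least `var_retained` of the total
#' variance, then k-means (multiple restarts) for each K in `K_range` and
#' the Bayesian information criterion `n*ln(WSS/n) + K*ln(n)` to pick the
#' number of clusters.
#'
#' @param markers a [marker_matrix()].
#' @param K_range integer vector of cluster counts to try.
#' @param var_retained fraction of variance the retained PCs must cover.
#' @param nstart k-means restarts.
#' @return Object of class `dapc_clusters`: list with `assignments` (named
#'   integer vector for the best K), `best_K`, `BIC` (named vector),
#'   `scores` (retained PC scores), `n_pcs`, `all_assignments`.
#' @export
find_clusters <- function(markers, K_range = 1:8, var_retained = 0.9,
                          nstart = 20L) {
  stopifnot(inherits(markers, "marker_matrix"))
  m <- markers$calls
  for (j in seq_len(ncol(m))) {
    mis <- is.na(m[, j])
    if (any(mis)) m[mis, j] <- mean(m[, j], na.rm = TRUE)
  }
  n <- nrow(m)
  if (max(K_range) >= n)
    stop("K_max must be smaller than the number of individuals",
         call. = FALSE)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  npc <- min(which(cum >= var_retained))
  sc <- pc$x[, seq_len(npc), drop = FALSE]
  bic <- stats::setNames(numeric(length(K_range)), K_range)
  all_assign <- list()
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    if (K == 1L) {
      wss <- sum(scale(sc, scale = FALSE)^2)
      cl <- rep(1L, n)
    } else {
      km <- stats::kmeans(sc, centers = K, nstart = nstart, iter.max = 100L)
      wss <- km$tot.withinss
      cl <- km$cluster
    }
    bic[i] <- n * log(wss / n) + K * log(n)
    all_assign[[as.character(K)]] <- stats::setNames(cl, rownames(m))
  }
  bk <- K_range[which.min(bic)]
  structure(
    list(assignments = all_assign[[as.character(bk)]], best_K = bk,
         BIC = bic, scores = sc, n_pcs = npc,
         all_assignments = all_assign),
    class = "dapc_clusters")
}

#' @export
print.dapc_clusters <- function(x, ...) {
  cat("Cluster search: best K =", x$best_K, "on", x$n_pcs,
      "retained PCs\n")
  print(round(x$BIC, 2))
  invisible(x)
}

#' Discriminant axes for given cluster assignments
#'
#' Linear discriminant analysis on the retained principal components,
#' returning individual coordinates on the discriminant axes and the
#' fraction of between-group variance each axis carries.
#'
#' @param clusters a `dapc_clusters` result (or any list with `scores`).
#' @param assignments optional alternative grouping (defaults to the best-K
#'   assignment of `clusters`).
#' @return Object of class `dapc_axes`: list with `coordinates` (individuals
#'   x discriminants), `var_fraction` (per-axis, sums to 1),
#'   `percent_first_two` (percent of discriminated variance on LD1+LD2),
#'   `lda` (the underlying fit).
#' @export
dapc_axes <- function(clusters, assignments = NULL) {
  grp <- if (is.null(assignments)) clusters$assignments else assignments
  grp <- factor(grp)
  if (nlevels(grp) < 2L)
    stop("discriminant analysis needs >= 2 clusters", call. = FALSE)
  if (any(table(grp) < 2L))
    stop("every cluster needs >= 2 members", call. = FALSE)
  fit <- MASS::lda(clusters$scores, grouping = grp)
  pred <- stats::predict(fit)
  vf <- fit$svd^2 / sum(fit$svd^2)
  structure(
    list(coordinates = pred$x, var_fraction = vf,
         percent_first_two = 100 * sum(vf[seq_len(min(2L, length(vf)))]),
         lda = fit),
    class = "dapc_axes")
}

#' @export
print.dapc_axes <- function(x, ...) {
  cat(sprintf(
    "Discriminant analysis: %d axes; first two describe %.2f%% of the\n",
    length(x$var_fraction), x$percent_first_two))
  cat("between-cluster variance\n")
  invisible(x)
}
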