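# Redundancy analysis and two-block variation partitioning.
#
# RDA here is multivariate least squares of the centred response matrix on
# a predictor block; the explained fraction R2 =
# trace(fitted' fitted)/trace(Y'Y) and the Ezekiel adjustment
# adjR2 = 1 - (1-R2)(n-1)/(n-1-m) give the building blocks for the
# standard two-block partition into pure and shared fractions.

# drop collinear columns (QR pivoting) from a centred predictor matrix
drop_collinear <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    warning("dropping ", ncol(X) - qr_x$rank,
            " collinear predictor column(s)")
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

#' Redundancy analysis (RDA)
#'
#' Multivariate least squares of the centred response matrix on the centred
#' predictor block; canonical axes come from the eigen-decomposition of the
#' fitted values.
#'
#' @param Y numeric response matrix (rows = units); centred internally.
#' @param X numeric predictor matrix; centred (and optionally standardised)
#'   internally; collinear columns are dropped with a warning.
#' @param standardize standardise predictor columns to unit variance.
#' @return Object of class `rda_model`: list with `R2`, `adj_R2`, `m`
#'   (predictor count used), `n`, `eig` (canonical eigenvalues), `axes`
#'   (site scores on canonical axes), `fitted`.
#' @export
rda <- function(Y, X, standardize = TRUE) {
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  X <- scale(as.matrix(X), center = TRUE, scale = standardize)
  # constant columns scale to NaN; drop them
  keep <- colSums(!is.finite(X)) == 0L
  X <- X[, keep, drop = FALSE]
  X <- drop_collinear(X)
  n <- nrow(Y)
  m <- ncol(X)
  if (m == 0L) stop("no usable predictor columns", call. = FALSE)
  if (n != nrow(X)) stop("Y and X row mismatch", call. = FALSE)
  fit <- qr.fitted(qr(X), Y)
  ss_tot <- sum(Y^2)
  r2 <- if (ss_tot > 0) sum(fit^2) / ss_tot else 0
  adj <- 1 - (1 - r2) * (n - 1) / (n - 1 - m)
  sv <- svd(fit)
  pos <- sv$d^2 > 1e-10 * max(sv$d^2, 1)
  structure(
    list(R2 = r2, adj_R2 = adj, m = m, n = n,
         eig = (sv$d^2 / (n - 1))[pos],
         axes = (sv$u %*% diag(sv$d, length(sv$d)))[, pos, drop = FALSE],
         fitted = fit),
    class = "rda_model")
}

#' @export
print.rda_model <- function(x, ...) {
  cat(sprintf("RDA: R2 = %.4f, adjusted R2 = %.4f (n = %d, m = %d)\n",
              x$R2, x$adj_R2, x$n, x$m))
  invisible(x)
}

#' Two-block variation partitioning by partial RDA
#'
#' Decomposes the adjusted explained variance of `Y` into the pure
#' environmental fraction \[a\], the spatially structured environmental
#' fraction \[b\], the pure geographical fraction \[c\] and the residual
#' \[d\], from the three marginal models:
#' `[a+b+c] = adjR2(Y ~ E+G)`, `[a+b] = adjR2(Y ~ E)`,
#' `[b+c] = adjR2(Y ~ G)`; then `a = [a+b+c] - [b+c]`,
#' `c = [a+b+c] - [a+b]`, `b = [a+b] + [b+c] - [a+b+c]`,
#' `d = 1 - [a+b+c]`. Individual fractions can be slightly negative
#' (adjusted-R2 artifact) and are reported as computed.
#'
#' @param Y response matrix (e.g. centred 0/1 band matrix).
#' @param E environmental predictor block.
#' @param G geographical predictor block (e.g. lon, lat).
#' @param standardize standardise predictors.
#' @return Object of class `partition_result`: list with `fractions`
#'   (named a, b, c, d), `marginal` (the three adjusted R2), `R2`
#'   (unadjusted counterparts), `n`, `m_E`, `m_G`.
#' @export
varpart <- function(Y, E, G, standardize = TRUE) {
  Y <- as.matrix(Y); E <- as.matrix(E); G <- as.matrix(G)
  if (ncol(E) == 0L || ncol(G) == 0L)
    stop("both predictor blocks must be non-empty", call. = FALSE)
  n <- nrow(Y)
  if (ncol(E) + ncol(G) >= n - 1L)
    stop("combined predictor count must be below n - 1", call. = FALSE)
  m_eg <- rda(Y, cbind(E, G), standardize)
  m_e <- rda(Y, E, standardize)
  m_g <- rda(Y, G, standardize)
  abc <- m_eg$adj_R2; ab <- m_e$adj_R2; bc <- m_g$adj_R2
  fr <- c(a = abc - bc, b = ab + bc - abc, c = abc - ab, d = 1 - abc)
  structure(
    list(fractions = fr,
         marginal = c(`a+b+c` = abc, `a+b` = ab, `b+c` = bc),
         R2 = c(`a+b+c` = m_eg$R2, `a+b` = m_e$R2, `b+c` = m_g$R2),
         n = n, m_E = m_e$m, m_G = m_g$m),
    class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("Variation partitioning (adjusted R2 fractions):\n")
  cat(sprintf("  [a] pure environment:              %7.4f\n",
              x$fractions["a"]))
  cat(sprintf("  [b] spatially structured environment: %7.4f\n",
              x$fractions["b"]))
  cat(sprintf("  [c] pure geography:                %7.4f\n",
              x$fractions["c"]))
  cat(sprintf("  [d] residual:                      %7.4f\n",
              x$fractions["d"]))
  invisible(x)
}

#' Permutation test for a variation-partitioning fraction
#'
#' Marginal fractions (`"a+b+c"`, `"a+b"`, `"b+c"`) are tested by permuting
#' rows of `Y`; conditional fractions (`"a"` = E given G, `"c"` = G given
#' E) by Freedman-Lane residual permutation: residuals of the reduced model
#' are permuted, added back to its fitted values, and the semipartial R2 of
#' the added block recomputed. Fraction `"b"` has no direct test and is
#' refused. P-values carry the +1 correction.
#'
#' @param Y,E,G as in [varpart()].
#' @param fraction one of `"a+b+c"`, `"a+b"`, `"b+c"`, `"a"`, `"c"`.
#' @param n_permutations permutation count (default 999).
#' @param standardize standardise predictors.
#' @return List with `fraction`, `statistic` (observed semipartial or
#'   marginal R2), `p`, `permutations`.
#' @export
permutation_test_fraction <- function(Y, E, G, fraction,
                                      n_permutations = 999L,
                                      standardize = TRUE) {
  fraction <- match.arg(fraction, c("a+b+c", "a+b", "b+c", "a", "c", "b"))
  if (fraction == "b")
    stop("fraction [b] has no direct permutation test", call. = FALSE)
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  E <- as.matrix(E); G <- as.matrix(G)
  n <- nrow(Y)
  prep <- function(M) {
    M <- scale(M, center = TRUE, scale = standardize)
    M <- M[, colSums(!is.finite(M)) == 0L, drop = FALSE]
    drop_collinear(M)
  }
  r2_of <- function(Yp, X) {
    f <- qr.fitted(qr(X), scale(Yp, center = TRUE, scale = FALSE))
    sum(f^2) / sum(scale(Yp, center = TRUE, scale = FALSE)^2)
  }
  if (fraction %in% c("a+b+c", "a+b", "b+c")) {
    X <- switch(fraction,
                "a+b+c" = prep(cbind(E, G)),
                "a+b" = prep(E),
                "b+c" = prep(G))
    obs <- r2_of(Y, X)
    perm <- replicate(n_permutations, r2_of(Y[sample.int(n), , drop = FALSE],
                                            X))
  } else {
    full <- prep(cbind(E, G))
    red <- if (fraction == "a") prep(G) else prep(E)
    qr_red <- qr(red)
    fit_red <- qr.fitted(qr_red, Y)
    res_red <- Y - fit_red
    semipartial <- function(Yp) {
      r2_of_mat <- function(X) {
        Ypc <- scale(Yp, center = TRUE, scale = FALSE)
        f <- qr.fitted(qr(X), Ypc)
        sum(f^2) / sum(Ypc^2)
      }
      r2_of_mat(full) - r2_of_mat(red)
    }
    obs <- semipartial(Y)
    perm <- replicate(n_permutations, {
      Yp <- fit_red + res_red[sample.int(n), , drop = FALSE]
      semipartial(Yp)
    })
  }
  list(fraction = fraction, statistic = obs,
       p = (1 + sum(perm >= obs)) / (1 + n_permutations),
       permutations = n_permutations)
}
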