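# Univariate logistic environmental association (Samb́ada-style): one
# logistic model of band presence per locus x environmental variable, Wald
# and likelihood-ratio (G) tests, Nagelkerke pseudo-R2, Bonferroni control.

#' Nagelkerke pseudo-R2
#'
#' Cox-Snell `R2_CS = 1 - exp(2*(LL0 - LL1)/n)` rescaled by its maximum
#' `1 - exp(2*LL0/n)` so a perfect fit reaches 1.
#'
#' @param LL0 intercept-only log-likelihood.
#' @param LL1 full-model log-likelihood (>= LL0).
#' @param n number of observations.
#' @return Pseudo-R2 in \[0, 1\].
#' @export
nagelkerke_r2 <- function(LL0, LL1, n) {
  stopifnot(n >= 1)
  r2_cs <- 1 - exp(2 * (LL0 - LL1) / n)
  denom <- 1 - exp(2 * LL0 / n)
  if (denom <= 0) return(0)
  max(min(r2_cs / denom, 1), 0)
}

#' Univariate logistic fit of a binary response on one predictor
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via `glm.fit`, convergence tolerance 1e-8) with the Wald test
#' `(beta1/se)^2 ~ chi2_1`, the likelihood-ratio test `G = 2*(LL1 - LL0) ~
#' chi2_1`, and Nagelkerke's pseudo-R2. Complete or quasi-complete
#' separation is flagged (`diverged = TRUE`); with `firth = TRUE` a
#' Jeffreys-prior penalised fit is used instead, which keeps the estimates
#' finite.
#'
#' @param y binary 0/1 vector (both classes present).
#' @param x numeric predictor (non-constant).
#' @param firth use Firth's penalised likelihood.
#' @return Object of class `logistic_fit`: list with `beta0`, `beta1`,
#'   `se0`, `se1`, `LL0`, `LL1`, `wald_p`, `g_p`, `nagelkerke_r2`, `n`,
#'   `diverged`, `firth`.
#' @export
fit_logistic <- function(y, x, firth = FALSE) {
  y <- as.numeric(y)
  x <- as.numeric(x)
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  if (length(unique(y)) < 2L)
    stop("response has a single class", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("constant predictor", call. = FALSE)
  n <- length(y)
  X <- cbind(1, x)
  if (!firth) {
    fit <- stats::glm.fit(X, y, family = stats::binomial(),
                          control = stats::glm.control(epsilon = 1e-8,
                                                       maxit = 100L))
    beta <- fit$coefficients
    mu <- fit$fitted.values
    w <- mu * (1 - mu)
    XtWX <- crossprod(X, X * w)
    vc <- tryCatch(chol2inv(chol(XtWX)), error = function(e)
      matrix(NA_real_, 2L, 2L))
    se <- sqrt(diag(vc))
    # frank divergence, or quasi-separation (fitted probabilities at the
    # boundary inflate the Wald SE — Hauck-Donner effect)
    diverged <- !fit$converged || any(abs(beta) > 25) ||
      any(!is.finite(se)) || any(se > 1e3) ||
      any(mu > 1 - 1e-3) || any(mu < 1e-3)
  } else {
    beta <- c(0, 0)
    for (it in seq_len(200L)) {
      eta <- drop(X %*% beta)
      mu <- 1 / (1 + exp(-eta))
      w <- mu * (1 - mu)
      XtWX <- crossprod(X, X * w)
      vc <- chol2inv(chol(XtWX))
      # hat diagonal of the weighted design
      H <- (X %*% vc) * X * w
      h <- rowSums(H)
      U <- crossprod(X, y - mu + h * (0.5 - mu))
      step <- drop(vc %*% U)
      beta <- beta + step
      if (max(abs(step)) < 1e-8) break
    }
    mu <- 1 / (1 + exp(-drop(X %*% beta)))
    w <- mu * (1 - mu)
    vc <- chol2inv(chol(crossprod(X, X * w)))
    se <- sqrt(diag(vc))
    diverged <- FALSE
  }
  eps <- 1e-12
  LL1 <- sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
  p0 <- mean(y)
  LL0 <- n * (p0 * log(p0) + (1 - p0) * log(1 - p0))
  G <- max(2 * (LL1 - LL0), 0)
  wald <- (beta[2L] / se[2L])^2
  structure(
    list(beta0 = unname(beta[1L]), beta1 = unname(beta[2L]),
         se0 = se[1L], se1 = se[2L], LL0 = LL0, LL1 = LL1,
         wald_p = stats::pchisq(wald, 1L, lower.tail = FALSE),
         g_p = stats::pchisq(G, 1L, lower.tail = FALSE),
         nagelkerke_r2 = nagelkerke_r2(LL0, LL1, n),
         n = n, diverged = diverged, firth = firth),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logit(p) = %.4f + %.4f x  (n = %d%s)\n", x$beta0, x$beta1,
              x$n, if (x$diverged) ", SEPARATION" else ""))
  cat(sprintf("Wald P = %.4g, G P = %.4g, Nagelkerke R2 = %.4f\n",
              x$wald_p, x$g_p, x$nagelkerke_r2))
  invisible(x)
}

#' Locus-by-variable environmental association scan
#'
#' Fits one univariate logistic model of band presence on each
#' environmental variable for every locus; individuals inherit the
#' environmental values of their population. Significance requires BOTH the
#' Wald and the likelihood-ratio p-value below the Bonferroni threshold
#' `alpha / (n_loci x n_variables)` (the divisor counts all loci, including
#' skipped monomorphic ones, times all variables). Monomorphic loci are
#' skipped with a reason.
#'
#' @param markers a [marker_matrix()].
#' @param env an [env_table()] with one row per population.
#' @param alpha family-wise error level (default 0.01).
#' @param variables which environmental columns to use (defaults to all
#'   declared variables, excluding lon/lat).
#' @param firth fall back to Firth's penalised fit for separated loci.
#' @return Object of class `association_table`: data frame with one row per
#'   locus x variable (`locus`, `variable`, `beta0`, `beta1`, `wald_p`,
#'   `g_p`, `nagelkerke_r2`, `diverged`, `significant`); attributes
#'   `threshold`, `n_models`, `skipped` (loci with reasons).
#' @export
association_scan <- function(markers, env, alpha = 0.01,
                             variables = NULL, firth = FALSE) {
  stopifnot(inherits(markers, "marker_matrix"), inherits(env, "env_table"))
  if (is.null(variables))
    variables <- attr(env, "variable_names")
  pops <- markers$population_of
  if (!all(unique(pops) %in% rownames(env)))
    stop("no joinable units: marker populations missing from env table",
         call. = FALSE)
  L <- ncol(markers$calls)
  V <- length(variables)
  n_models <- L * V
  threshold <- alpha / n_models
  xmat <- as.matrix(as.data.frame(env)[pops, variables, drop = FALSE])
  res <- vector("list", n_models)
  skipped <- character()
  k <- 0L
  for (l in seq_len(L)) {
    y <- markers$calls[, l]
    yy <- y[!is.na(y)]
    if (length(unique(yy)) < 2L) {
      skipped <- c(skipped, stats::setNames("monomorphic",
                                            markers$locus_ids[l]))
      next
    }
    for (v in seq_len(V)) {
      fit <- fit_logistic(y, xmat[, v], firth = FALSE)
      if (fit$diverged && firth) fit <- fit_logistic(y, xmat[, v],
                                                     firth = TRUE)
      k <- k + 1L
      res[[k]] <- data.frame(
        locus = markers$locus_ids[l], variable = variables[v],
        beta0 = fit$beta0, beta1 = fit$beta1,
        wald_p = fit$wald_p, g_p = fit$g_p,
        nagelkerke_r2 = fit$nagelkerke_r2,
        diverged = fit$diverged,
        significant = !fit$diverged &&
          fit$wald_p < threshold && fit$g_p < threshold)
    }
  }
  out <- do.call(rbind, res[seq_len(k)])
  if (is.null(out))
    out <- data.frame(locus = character(), variable = character(),
                      beta0 = numeric(), beta1 = numeric(),
                      wald_p = numeric(), g_p = numeric(),
                      nagelkerke_r2 = numeric(), diverged = logical(),
                      significant = logical())
  structure(out, class = c("association_table", "data.frame"),
            threshold = threshold, n_models = n_models, alpha = alpha,
            skipped = skipped)
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf(
    "Association scan: %d models, Bonferroni threshold %.4g (alpha %.3g)\n",
    attr(x, "n_models"), attr(x, "threshold"), attr(x, "alpha")))
  sig <- x[x$significant %in% TRUE, , drop = FALSE]
  cat(nrow(sig), "significant locus-variable pairs;",
      length(attr(x, "skipped")), "loci skipped\n")
  if (nrow(sig))
    print(as.data.frame(sig)[, c("locus", "variable", "nagelkerke_r2",
                                 "g_p")], row.names = FALSE)
  invisible(x)
}

#' Fitted logistic curve for one locus-variable pair
#'
#' Convenience export of plotting data (x grid and fitted band-presence
#' probability) for association figures.
#'
#' @param fit a `logistic_fit`.
#' @param x_range numeric length-2 range of the predictor.
#' @param length_out grid size.
#' @return Data frame with `x` and `p`.
#' @export
logistic_curve <- function(fit, x_range, length_out = 100L) {
  xg <- seq(x_range[1L], x_range[2L], length.out = length_out)
  data.frame(x = xg, p = 1 / (1 + exp(-(fit$beta0 + fit$beta1 * xg))))
}
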