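# Simplified BayeScan-style hierarchical model for dominant markers.
#
# Data: per locus i and population j, the number of band-absent individuals
# m_ij out of n_ij; absence probability is (1-p_ij)^2 under Hardy-Weinberg.
# Model: p_ij ~ Beta(theta_ij * pbar_i, theta_ij * (1 - pbar_i)) with
# theta_ij = 1/F_ij - 1 and logit(F_ij) = alpha_i * delta_i + beta_j.
# A reversible-jump indicator delta_i includes or excludes the locus-level
# selection effect alpha_i; prior odds are 10:1 in favour of neutrality
# (P(delta=1) = 1/11). beta_j ~ N(-1, 1.8^2), alpha_i ~ N(0, 2^2).
# Posterior odds PO_i = P(delta_i=1 | data) / P(delta_i=0 | data).

logit <- function(x) log(x / (1 - x))
inv_logit <- function(x) 1 / (1 + exp(-x))

# log Beta(p | theta*pbar, theta*(1-pbar)) density, vectorised
ldbeta_bn <- function(p, pbar, theta)
  stats::dbeta(p, theta * pbar, theta * (1 - pbar), log = TRUE)

#' Bayesian posterior-odds outlier scan for dominant markers
#'
#' A reversible-jump MCMC over a hierarchical Balding-Nichols model in
#' which each locus either shares the genome-wide differentiation (set by
#' population effects `beta_j` on the logit of F) or carries an additional
#' locus-specific selection effect `alpha_i`. The posterior odds of the
#' selection model, `PO = P(delta=1|data)/P(delta=0|data)`, flag a locus as
#' under selection when `log10(PO)` exceeds `log10_po_threshold` (1.5, the
#' conventional "very strong evidence" bar). With no data the posterior
#' odds collapse to the prior odds, log10(PO) = -1.
#'
#' @param markers a [marker_matrix()].
#' @param n_iter post-burn-in sweeps retained (after thinning = 1).
#' @param burn_in discarded initial sweeps.
#' @param prior_odds_neutral prior odds of neutrality over selection
#'   (default 10).
#' @param log10_po_threshold decision threshold on log10 posterior odds.
#' @param sd_alpha prior (and RJ proposal) sd of the locus effect.
#' @param po_cap cap reported when the indicator never leaves 1 (mirrors
#'   the conventional capped display).
#' @param seed optional integer seed for the chain.
#' @return Object of class `bayescan_result`: data frame with `locus`,
#'   `post_prob_selection`, `log10_PO`, `alpha_mean`, `outlier`; attributes
#'   `beta_mean`, `convergence_warning`.
#' @export
bayescan_lite <- function(markers, n_iter = 4000L, burn_in = 2000L,
                          prior_odds_neutral = 10,
                          log10_po_threshold = 1.5,
                          sd_alpha = 2, po_cap = 1000,
                          seed = NULL) {
  stopifnot(inherits(markers, "marker_matrix"))
  if (!is.null(seed)) set.seed(seed)
  pops <- unique(markers$population_of)
  P <- length(pops)
  Lall <- ncol(markers$calls)
  m_abs <- n_sc <- matrix(0, Lall, P, dimnames = list(markers$locus_ids,
                                                      pops))
  for (p in pops) {
    sub <- markers$calls[markers$population_of == p, , drop = FALSE]
    n_sc[, p] <- colSums(!is.na(sub))
    m_abs[, p] <- colSums(sub == 0, na.rm = TRUE)
  }
  band <- ifelse(n_sc > 0, 1 - m_abs / n_sc, NA)
  # monomorphic loci carry no information and are excluded; loci with no
  # scored individuals at all are kept so their indicator recovers the prior
  poly <- apply(band, 1L, function(b) {
    b <- b[!is.na(b)]
    length(b) == 0L || (any(b > 0) && any(b < 1))
  })
  loci <- markers$locus_ids[poly]
  m_abs <- m_abs[poly, , drop = FALSE]
  n_sc <- n_sc[poly, , drop = FALSE]
  L <- length(loci)
  has_data <- n_sc > 0
  prior_sel <- 1 / (1 + prior_odds_neutral)

  # initial values
  frac <- ifelse(has_data, m_abs / pmax(n_sc, 1), 0.5)
  pm <- 1 - sqrt(pmin(pmax(frac, 1 / (2 * (n_sc + 1))), 1 - 1e-4))
  pm <- pmin(pmax(pm, 0.02), 0.98)          # p_ij
  pbar <- pmin(pmax(rowMeans(pm), 0.02), 0.98)
  beta <- rep(-1, P)
  alpha <- rep(0, L)
  delta <- rep(FALSE, L)

  llik_bin <- function(pmat) {
    # binomial log-likelihood of absence counts, 0 where no data
    ll <- m_abs * 2 * log(1 - pmat) + (n_sc - m_abs) * log(1 - (1 - pmat)^2)
    ll[!has_data] <- 0
    ll
  }
  theta_of <- function(a, b) {
    Fij <- inv_logit(outer(a, b, "+"))
    Fij <- pmin(pmax(Fij, 1e-6), 1 - 1e-6)
    1 / Fij - 1
  }

  keep_dsum <- numeric(L)
  keep_asum <- numeric(L)
  keep_bsum <- numeric(P)
  kept <- 0L
  d_trace_half <- matrix(0, 2L, P)  # split-chain beta means

  theta <- theta_of(alpha * delta, beta)
  ll_p <- llik_bin(pm)
  lp_beta_pm <- ldbeta_bn(pm, pbar, theta)

  total <- burn_in + n_iter
  for (it in seq_len(total)) {
    # --- update p_ij (random-walk on logit), vectorised over all cells
    prop <- inv_logit(logit(pm) + stats::rnorm(L * P, 0, 0.4))
    prop <- pmin(pmax(prop, 1e-6), 1 - 1e-6)
    ll_new <- llik_bin(prop)
    lp_new <- ldbeta_bn(prop, pbar, theta)
    # Jacobian of the logit walk: dlogit is symmetric on the logit scale,
    # density transform adds log(p(1-p)) terms
    lacc <- (ll_new + lp_new + log(prop) + log1p(-prop)) -
      (ll_p + lp_beta_pm + log(pm) + log1p(-pm))
    acc <- matrix(log(stats::runif(L * P)) < lacc, L, P)
    pm[acc] <- prop[acc]
    ll_p[acc] <- ll_new[acc]
    lp_beta_pm[acc] <- lp_new[acc]

    # --- update pbar_i (random-walk on logit), prior Uniform(0,1)
    pb_prop <- inv_logit(logit(pbar) + stats::rnorm(L, 0, 0.3))
    pb_prop <- pmin(pmax(pb_prop, 1e-4), 1 - 1e-4)
    lp_old <- rowSums(lp_beta_pm)
    lp_prop <- rowSums(ldbeta_bn(pm, pb_prop, theta))
    lacc <- (lp_prop + log(pb_prop) + log1p(-pb_prop)) -
      (lp_old + log(pbar) + log1p(-pbar))
    acc <- log(stats::runif(L)) < lacc
    pbar[acc] <- pb_prop[acc]
    lp_beta_pm[acc, ] <- ldbeta_bn(pm[acc, , drop = FALSE],
                                   pbar[acc], theta[acc, , drop = FALSE])

    # --- update alpha_i where delta_i = 1
    sel <- which(delta)
    if (length(sel)) {
      a_prop <- alpha
      a_prop[sel] <- alpha[sel] + stats::rnorm(length(sel), 0, 0.5)
      th_prop <- theta_of(a_prop * delta, beta)
      lp_prop <- rowSums(ldbeta_bn(pm[sel, , drop = FALSE], pbar[sel],
                                   th_prop[sel, , drop = FALSE]))
      lp_old <- rowSums(lp_beta_pm[sel, , drop = FALSE])
      lacc <- lp_prop - lp_old +
        stats::dnorm(a_prop[sel], 0, sd_alpha, log = TRUE) -
        stats::dnorm(alpha[sel], 0, sd_alpha, log = TRUE)
      acc <- log(stats::runif(length(sel))) < lacc
      chg <- sel[acc]
      if (length(chg)) {
        alpha[chg] <- a_prop[chg]
        theta[chg, ] <- th_prop[chg, , drop = FALSE]
        lp_beta_pm[chg, ] <- ldbeta_bn(pm[chg, , drop = FALSE],
                                       pbar[chg],
                                       theta[chg, , drop = FALSE])
      }
    }

    # --- update beta_j one at a time
    for (j in seq_len(P)) {
      b_prop <- beta
      b_prop[j] <- beta[j] + stats::rnorm(1L, 0, 0.25)
      th_prop_j <- inv_logit(alpha * delta + b_prop[j])
      th_prop_j <- 1 / pmin(pmax(th_prop_j, 1e-6), 1 - 1e-6) - 1
      lp_prop <- ldbeta_bn(pm[, j], pbar, th_prop_j)
      lacc <- sum(lp_prop - lp_beta_pm[, j]) +
        stats::dnorm(b_prop[j], -1, 1.8, log = TRUE) -
        stats::dnorm(beta[j], -1, 1.8, log = TRUE)
      if (log(stats::runif(1L)) < lacc) {
        beta[j] <- b_prop[j]
        theta[, j] <- th_prop_j
        lp_beta_pm[, j] <- lp_prop
      }
    }

    # --- reversible jump on delta_i (proposal for alpha = its prior, so
    # proposal and prior cancel; acceptance is likelihood ratio x prior
    # odds of the indicator)
    a_birth <- stats::rnorm(L, 0, sd_alpha)
    a_new <- ifelse(delta, 0, a_birth)
    th_new <- theta_of(a_new * !delta, beta)  # toggled state
    lp_new_mat <- ldbeta_bn(pm, pbar, th_new)
    lp_ratio <- rowSums(lp_new_mat) - rowSums(lp_beta_pm)
    l_prior <- ifelse(delta, log1p(-prior_sel) - log(prior_sel),
                      log(prior_sel) - log1p(-prior_sel))
    acc <- log(stats::runif(L)) < (lp_ratio + l_prior)
    if (any(acc)) {
      delta[acc] <- !delta[acc]
      alpha[acc] <- ifelse(delta[acc], a_birth[acc], 0)
      theta[acc, ] <- th_new[acc, , drop = FALSE]
      lp_beta_pm[acc, ] <- lp_new_mat[acc, , drop = FALSE]
    }

    if (it > burn_in) {
      kept <- kept + 1L
      keep_dsum <- keep_dsum + delta
      keep_asum <- keep_asum + alpha
      keep_bsum <- keep_bsum + beta
      half <- if (kept <= n_iter / 2) 1L else 2L
      d_trace_half[half, ] <- d_trace_half[half, ] + beta
    }
  }
  post_sel <- keep_dsum / kept
  po <- ifelse(post_sel >= 1, po_cap,
               pmin(post_sel / (1 - post_sel), po_cap))
  po <- pmax(po, 1 / po_cap)
  halves <- d_trace_half / (kept / 2)
  conv_warn <- any(abs(halves[1L, ] - halves[2L, ]) > 0.5)
  if (conv_warn)
    warning("split-chain disagreement in population effects beta; ",
            "consider longer chains")
  out <- data.frame(
    locus = loci,
    post_prob_selection = post_sel,
    log10_PO = log10(po),
    alpha_mean = keep_asum / kept,
    outlier = log10(po) > log10_po_threshold)
  structure(out, class = c("bayescan_result", "data.frame"),
            beta_mean = stats::setNames(keep_bsum / kept, pops),
            convergence_warning = conv_warn,
            excluded = markers$locus_ids[!poly])
}

#' @export
print.bayescan_result <- function(x, ...) {
  cat("Posterior-odds outlier scan:", nrow(x), "loci;",
      sum(x$outlier), "with log10(PO) above threshold\n")
  if (any(x$outlier))
    print(as.data.frame(x)[x$outlier, ], row.names = FALSE)
  invisible(x)
}
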