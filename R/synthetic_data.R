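# Island-model dominant-marker and environmental-gradient generators. The
# coalescent sequence generator lives in coalescent.R.

#' Simulate spatially structured environmental covariates
#'
#' Each variable is a linear gradient along the projection of the
#' population coordinates onto a direction, plus Gaussian noise; lon/lat
#' are included. With `gradient = 0` a variable is independent of
#' geography; with `noise_sd = 0` it is perfectly collinear with the
#' coordinate projection.
#'
#' @param n_pop number of populations.
#' @param n_var number of environmental variables.
#' @param gradient gradient strength (scalar or per-variable vector); units
#'   of response per unit of projected coordinate.
#' @param noise_sd Gaussian noise sd (scalar or per-variable).
#' @param coords optional n_pop x 2 matrix of lon/lat; defaults to a
#'   diagonal transect.
#' @param var_names variable names (defaults to `env1..env<n_var>`).
#' @return An [env_table()] with one row per population (`pop1..popP`).
#' @export
simulate_env <- function(n_pop = 8L, n_var = 7L, gradient = 1,
                         noise_sd = 0.3, coords = NULL,
                         var_names = NULL) {
  if (is.null(coords)) {
    s <- seq(0, 1, length.out = n_pop)
    coords <- cbind(lon = 121 + s, lat = 22 + 2.5 * s)
  }
  gradient <- rep_len(gradient, n_var)
  noise_sd <- rep_len(noise_sd, n_var)
  if (is.null(var_names)) var_names <- paste0("env", seq_len(n_var))
  proj <- coords[, 1L] + coords[, 2L]
  proj <- if (stats::sd(proj) > 0) (proj - mean(proj)) / stats::sd(proj)
          else proj * 0
  vars <- vapply(seq_len(n_var), function(v)
    gradient[v] * proj + stats::rnorm(n_pop, 0, noise_sd[v]),
    numeric(n_pop))
  vars <- matrix(vars, nrow = n_pop,
                 dimnames = list(NULL, var_names))
  env_table(paste0("pop", seq_len(n_pop)), as.data.frame(vars),
            lon = coords[, 1L], lat = coords[, 2L])
}

#' Simulate a dominant-marker dataset under a Balding-Nichols island model
#'
#' Ancestral band-allele frequencies are drawn from `Beta(prior_a,
#' prior_b)`; per-population frequencies from the Balding-Nichols
#' distribution `Beta(p*(1-F)/F, (1-p)*(1-F)/F)` with `F = background_fst`.
#' Planted loci instead track an environmental gradient:
#' `logit(p_j) = logit(pbar) + coeff * standardized env value of population
#' j`. Each individual shows the band with probability `1 - (1-p)^2`
#' (dominant phenotype under Hardy-Weinberg). The default scale — 8
#' populations x 15 individuals x 500 loci, background FST 0.15, band
#' frequency prior Beta(0.6, 0.6) — mirrors a typical AFLP survey with
#' moderate differentiation and mean gene diversity near 0.28.
#'
#' @param env an [env_table()] with one row per population.
#' @param n_per number of individuals per population (scalar or vector).
#' @param n_loci number of loci.
#' @param background_fst island-model FST for non-planted loci, in (0,1).
#' @param planted data frame with columns `locus` (index), `variable`
#'   (env column name) and `coeff`, or NULL for none.
#' @param prior_a,prior_b Beta prior for ancestral band-allele frequencies.
#' @return List with `markers` (a [marker_matrix()]), `truth` (data frame
#'   of planted loci), `p_pop` (true per-population band-allele
#'   frequencies, loci x populations).
#' @export
simulate_aflp <- function(env, n_per = 15L, n_loci = 500L,
                          background_fst = 0.15, planted = NULL,
                          prior_a = 0.6, prior_b = 0.6) {
  stopifnot(inherits(env, "env_table"))
  pops <- rownames(env)
  P <- length(pops)
  n_per <- rep_len(n_per, P)
  if (!is.null(planted)) {
    stopifnot(all(planted$locus <= n_loci),
              all(planted$variable %in% attr(env, "variable_names")))
  }
  F <- background_fst
  stopifnot(F > 0, F < 1)
  pbar <- stats::rbeta(n_loci, prior_a, prior_b)
  pbar <- pmin(pmax(pbar, 0.02), 0.98)
  sc <- (1 - F) / F
  p_pop <- matrix(stats::rbeta(n_loci * P, rep(pbar, P) * sc,
                               rep(1 - pbar, P) * sc),
                  n_loci, P, dimnames = list(NULL, pops))
  if (!is.null(planted) && nrow(planted)) {
    for (r in seq_len(nrow(planted))) {
      l <- planted$locus[r]
      z <- scale(as.data.frame(env)[[planted$variable[r]]])[, 1L]
      b0 <- if (!is.null(planted$pbar)) logit(planted$pbar[r])
            else logit(pbar[l])
      p_pop[l, ] <- inv_logit(b0 + planted$coeff[r] * z)
    }
  }
  calls <- matrix(NA_real_, sum(n_per), n_loci)
  ids <- character(sum(n_per))
  popv <- character(sum(n_per))
  row <- 0L
  for (j in seq_len(P)) {
    idx <- row + seq_len(n_per[j])
    show_p <- 1 - (1 - p_pop[, j])^2
    calls[idx, ] <- t(matrix(stats::rbinom(n_loci * n_per[j],
                                           1L, rep(show_p, n_per[j])),
                             n_loci, n_per[j]))
    ids[idx] <- sprintf("%s_i%02d", pops[j], seq_len(n_per[j]))
    popv[idx] <- pops[j]
    row <- row + n_per[j]
  }
  dimnames(calls) <- list(ids, sprintf("L%04d", seq_len(n_loci)))
  truth <- if (is.null(planted)) {
    data.frame(locus = character(), variable = character(),
               coeff = numeric())
  } else {
    data.frame(locus = sprintf("L%04d", planted$locus),
               variable = planted$variable, coeff = planted$coeff)
  }
  list(markers = marker_matrix(calls, stats::setNames(popv, ids)),
       truth = truth, p_pop = p_pop)
}

#' Plant a high-differentiation locus into a marker matrix
#'
#' Replaces one locus with a Balding-Nichols draw whose realised
#' among-population variance is rescaled to the stated FST, so the plant
#' carries exactly the differentiation it is labelled with (a raw draw has
#' expectation `fst` but large spread across realisations). Phenotypes are
#' re-drawn as dominant band presence.
#'
#' @param markers a [marker_matrix()].
#' @param locus locus index or id to replace.
#' @param fst target FST of the planted locus.
#' @param pbar ancestral band-allele frequency of the plant.
#' @return The modified [marker_matrix()], with the true per-population
#'   band-allele frequencies in attribute `planted_p`.
#' @export
plant_fst_locus <- function(markers, locus = 1L, fst = 0.6, pbar = 0.5) {
  stopifnot(inherits(markers, "marker_matrix"))
  if (is.character(locus)) locus <- match(locus, markers$locus_ids)
  pops <- unique(markers$population_of)
  P <- length(pops)
  sc <- (1 - fst) / fst
  pj <- stats::rbeta(P, pbar * sc, (1 - pbar) * sc)
  # rescale-and-clamp until the realised variance ratio matches the target
  target <- fst * pbar * (1 - pbar)
  for (it in 1:8) {
    pj <- pbar + (pj - mean(pj)) * sqrt(target / max(stats::var(pj), 1e-12))
    pj <- pmin(pmax(pj, 0.02), 0.98)
    if (abs(stats::var(pj) - target) < 0.01 * target) break
  }
  for (j in seq_len(P)) {
    idx <- markers$population_of == pops[j]
    markers$calls[idx, locus] <- stats::rbinom(sum(idx), 1L,
                                               1 - (1 - pj[j])^2)
  }
  attr(markers, "planted_p") <- stats::setNames(pj, pops)
  markers
}
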