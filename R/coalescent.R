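# Internal n-coalescent machinery with infinite-sites mutation.
#
# A genealogy is simulated as a sequence of n-1 coalescent events; every
# branch is stored with the set of sampled tips beneath it. Mutations are
# either Poisson(theta/2 * branch length) (fixed-theta mode) or exactly S
# mutations placed multinomially along the tree proportional to branch
# length (fixed-S mode, DnaSP-style conditioning). Each mutation hits a
# fresh site, so a mutation is fully described by its carrier set.

# Simulate one genealogy. demography = "constant" or "sudden-expansion".
# Under sudden expansion (looking backward in time) the relative population
# size is 1 until t_expansion (units of 2N0 generations) and 1/growth_factor
# earlier, so coalescence accelerates by growth_factor beyond t_expansion.
sim_genealogy <- function(n, demography = "constant",
                          t_expansion = Inf, growth_factor = 1) {
  members <- lapply(seq_len(n), identity)
  tbirth <- numeric(n)
  t <- 0
  branches_members <- vector("list", 2L * (n - 1L))
  branch_len <- numeric(2L * (n - 1L))
  bi <- 0L
  k <- n
  while (k > 1L) {
    rate <- k * (k - 1) / 2
    if (demography == "sudden-expansion" && t < t_expansion) {
      wait <- stats::rexp(1L, rate)
      if (t + wait > t_expansion) {
        # crossed into the small pre-expansion population: restart the
        # memoryless wait at rate * growth_factor
        t <- t_expansion + stats::rexp(1L, rate * growth_factor)
      } else t <- t + wait
    } else {
      g <- if (demography == "sudden-expansion") growth_factor else 1
      t <- t + stats::rexp(1L, rate * g)
    }
    pick <- sample.int(k, 2L)
    i <- pick[1L]; j <- pick[2L]
    bi <- bi + 1L
    branches_members[[bi]] <- members[[i]]
    branch_len[bi] <- t - tbirth[i]
    bi <- bi + 1L
    branches_members[[bi]] <- members[[j]]
    branch_len[bi] <- t - tbirth[j]
    members[[i]] <- c(members[[i]], members[[j]])
    tbirth[i] <- t
    members[[j]] <- members[[k]]
    tbirth[j] <- tbirth[k]
    members <- members[-k]
    tbirth <- tbirth[-k]
    k <- k - 1L
  }
  list(branches = branches_members, lengths = branch_len,
       tmrca = t, total_length = sum(branch_len), n = n)
}

# Place mutations on a genealogy; returns list of carrier index vectors.
mutate_genealogy <- function(gen, theta = NULL, S = NULL) {
  if (!is.null(S)) {
    if (S == 0L) return(list())
    idx <- sample.int(length(gen$lengths), S, replace = TRUE,
                      prob = gen$lengths)
  } else {
    nm <- stats::rpois(1L, theta / 2 * gen$total_length)
    if (nm == 0L) return(list())
    idx <- sample.int(length(gen$lengths), nm, replace = TRUE,
                      prob = gen$lengths)
  }
  gen$branches[idx]
}

# Summary statistics from a list of mutation carrier sets.
# Returns n, S, k_bar, singletons per sequence (derived allele count 1),
# number of distinct haplotypes, and the 0/1 genotype matrix when asked.
coalescent_stats <- function(carriers, n, genotypes = FALSE) {
  S <- length(carriers)
  if (S == 0L) {
    out <- list(n = n, S = 0L, k_bar = 0, U = rep(0L, n), K = 1L)
    if (genotypes) out$X <- matrix(0L, n, 0L)
    return(out)
  }
  sizes <- lengths(carriers)
  k_bar <- sum(sizes * (n - sizes)) / (n * (n - 1) / 2)
  U <- rep(0L, n)
  singles <- unlist(carriers[sizes == 1L], use.names = FALSE)
  if (length(singles)) {
    tb <- tabulate(singles, nbins = n)
    U <- tb
  }
  X <- matrix(0L, n, S)
  for (s in seq_len(S)) X[carriers[[s]], s] <- 1L
  key <- apply(X, 1L, paste0, collapse = "")
  K <- length(unique(key))
  out <- list(n = n, S = S, k_bar = k_bar, U = U, K = K)
  if (genotypes) out$X <- X
  out
}

# One constant-size replicate conditioned on S segregating sites (fixed-S)
# or on theta (fixed-theta); returns coalescent_stats output.
sim_replicate_stats <- function(n, S = NULL, theta = NULL,
                                demography = "constant",
                                t_expansion = Inf, growth_factor = 1,
                                genotypes = FALSE) {
  gen <- sim_genealogy(n, demography, t_expansion, growth_factor)
  carriers <- mutate_genealogy(gen, theta = theta, S = S)
  coalescent_stats(carriers, n, genotypes = genotypes)
}

# pairwise-difference vector from a 0/1 genotype matrix
pair_diffs_binary <- function(X) {
  n <- nrow(X)
  if (ncol(X) == 0L) return(rep(0L, n * (n - 1L) / 2L))
  r <- rowSums(X)
  G <- tcrossprod(X)
  D <- outer(r, r, "+") - 2 * G
  as.integer(D[upper.tri(D)])
}

#' Simulate a coalescent alignment under the infinite-sites model
#'
#' Standard n-coalescent with exponential waiting times; under the
#' sudden-expansion demography the (backward-time) population size drops by
#' `growth_factor` at scaled time `tau_mut / theta` (so that `tau_mut` is the
#' expansion age in mutational units, 2*u*t per locus). `Poisson(theta/2 *
#' branch length)` mutations are placed on the genealogy, each at a fresh
#' site of a monomorphic background sequence.
#'
#' @param n number of sampled sequences.
#' @param theta per-locus scaled mutation rate (4*N0*u).
#' @param sites alignment length in bp; must be at least the realised number
#'   of segregating sites.
#' @param demography `"constant"` or `"sudden-expansion"`.
#' @param tau_mut expansion age in mutational units (sudden-expansion only).
#' @param growth_factor factor by which the population grew at the expansion.
#' @param population population label given to all samples.
#' @param prefix sample-id prefix.
#' @return An [aligned_sequence_set()].
#' @export
simulate_coalescent_alignment <- function(n, theta, sites = 1000L,
                                          demography = c("constant",
                                                         "sudden-expansion"),
                                          tau_mut = 2, growth_factor = 100,
                                          population = "pop1",
                                          prefix = "seq") {
  demography <- match.arg(demography)
  t_exp <- if (demography == "sudden-expansion") tau_mut / theta else Inf
  st <- sim_replicate_stats(n, theta = theta, demography = demography,
                            t_expansion = t_exp,
                            growth_factor = growth_factor,
                            genotypes = TRUE)
  if (st$S > sites)
    stop("realised segregating sites (", st$S, ") exceed requested ",
         "alignment length (", sites, ")", call. = FALSE)
  base <- rep("A", sites)
  pos <- sample.int(sites, st$S)
  seqs <- vapply(seq_len(n), function(i) {
    s <- base
    s[pos[st$X[i, ] == 1L]] <- "T"
    paste0(s, collapse = "")
  }, character(1L))
  ids <- sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
  aligned_sequence_set(ids, seqs,
                       stats::setNames(rep(population, n), ids))
}
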