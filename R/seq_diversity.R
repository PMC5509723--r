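#' Apply a site filter to an alignment
#'
#' Two policies for alignment columns containing gaps (`-`) or ambiguity
#' codes (`N`): `"exclude-gap-columns"` (complete deletion: every column
#' containing any gap/N is dropped before analysis, the default) or
#' `"pairwise-deletion"` (columns kept; statistics that admit it skip the
#' affected pairs site-wise).
#'
#' @param aln an [aligned_sequence_set()].
#' @param policy `"exclude-gap-columns"` or `"pairwise-deletion"`.
#' @return A list with `matrix` (character matrix, samples x retained sites),
#'   `effective_length` (number of retained columns), `policy`.
#' @export
filter_sites <- function(aln, policy = c("exclude-gap-columns",
                                         "pairwise-deletion")) {
  policy <- match.arg(policy)
  m <- do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
  rownames(m) <- aln$sample_ids
  if (policy == "exclude-gap-columns") {
    keep <- colSums(m == "-" | m == "N") == 0L
    m <- m[, keep, drop = FALSE]
  }
  list(matrix = m, effective_length = ncol(m), policy = policy)
}

#' Collapse an alignment into distinct haplotypes
#'
#' Identical post-filter sequences share a haplotype. Haplotypes are ordered
#' by decreasing total count, ties broken by first occurrence, and labelled
#' `H1, H2, ...`.
#'
#' @param aln an [aligned_sequence_set()].
#' @param policy site-filter policy, see [filter_sites()].
#' @return Object of class `haplotype_table`: list with `haplotype_ids`,
#'   `representative` (one sequence per haplotype, post-filter),
#'   `counts` (haplotype x population integer matrix), `n_total`,
#'   `assignment` (haplotype id per input sample), `effective_length`.
#' @export
collapse_haplotypes <- function(aln, policy = "exclude-gap-columns") {
  stopifnot(inherits(aln, "aln_set"))
  fs <- filter_sites(aln, policy)
  key <- apply(fs$matrix, 1L, paste0, collapse = "")
  first <- !duplicated(key)
  uniq <- key[first]
  tot <- as.vector(table(factor(key, levels = uniq)))
  ord <- order(-tot, seq_along(uniq))
  uniq <- uniq[ord]
  ids <- paste0("H", seq_along(uniq))
  assign <- ids[match(key, uniq)]
  pops <- aln$population_of
  counts <- table(factor(assign, levels = ids),
                  factor(pops, levels = unique(pops)))
  counts <- matrix(as.integer(counts), nrow = length(ids),
                   dimnames = dimnames(counts))
  structure(
    list(haplotype_ids = ids,
         representative = stats::setNames(uniq, ids),
         counts = counts,
         n_total = length(key),
         assignment = stats::setNames(assign, aln$sample_ids),
         effective_length = fs$effective_length),
    class = "haplotype_table")
}

#' Construct a haplotype table directly from counts
#'
#' Used when the haplotype composition is known (for instance from a
#' published table) without the underlying sequences.
#'
#' @param counts haplotype x population matrix of non-negative integers with
#'   dimnames.
#' @param representative optional named character vector of representative
#'   sequences.
#' @return A `haplotype_table`.
#' @export
haplotype_table <- function(counts, representative = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("haplotype counts must be non-negative integers", call. = FALSE)
  structure(
    list(haplotype_ids = rownames(counts),
         representative = representative,
         counts = counts,
         n_total = sum(counts),
         assignment = NULL,
         effective_length = NA_integer_),
    class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Haplotype table:", length(x$haplotype_ids), "haplotypes,",
      x$n_total, "sequences,", ncol(x$counts), "populations\n")
  print(x$counts)
  invisible(x)
}

#' Haplotype (gene) diversity with its standard deviation
#'
#' Unbiased estimator `Hd = n/(n-1) * (1 - sum p_i^2)` with the sampling
#' variance of Nei (1987, eq. 8.12):
#' `V = 2/(n(n-1)) * { 2(n-2) (sum p^3 - (sum p^2)^2) + sum p^2 - (sum p^2)^2 }`.
#'
#' @param counts integer vector of haplotype counts (one population), or a
#'   `haplotype_table` whose per-population columns are each summarised.
#' @return For a count vector, a named numeric `c(Hd=, sd=, n=)`; for a
#'   table, a data frame with one row per population plus a pooled row.
#' @export
haplotype_diversity <- function(counts) {
  if (inherits(counts, "haplotype_table")) {
    per <- t(apply(counts$counts, 2L, haplotype_diversity))
    pooled <- haplotype_diversity(rowSums(counts$counts))
    out <- as.data.frame(rbind(per, Pooled = pooled))
    out$population <- rownames(out)
    rownames(out) <- NULL
    return(out[, c("population", "Hd", "sd", "n")])
  }
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity undefined for n < 2", call. = FALSE)
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  hd <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  c(Hd = hd, sd = sqrt(max(v, 0)), n = n)
}

# pairwise difference counts between rows of a character site matrix,
# honouring pairwise deletion of gap/N sites when policy requires it
pairwise_diffs <- function(m, policy = "exclude-gap-columns") {
  n <- nrow(m)
  d <- matrix(0L, n, n)
  if (ncol(m) == 0L || n < 2L) return(d)
  miss <- m == "-" | m == "N"
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (policy == "pairwise-deletion") {
        ok <- !miss[i, ] & !miss[j, ]
        d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok])
      } else {
        d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
      }
    }
  }
  d
}

#' Nucleotide diversity summary
#'
#' Per-site nucleotide diversity from mean pairwise differences (`theta_pi`)
#' and from the number of segregating sites via Watterson's correction
#' (`theta_S = S / (a_n * L_eff)`, `a_n = sum_{i=1}^{n-1} 1/i`), with their
#' standard deviations (Nei 1987 eq. 10.7 for pi; Watterson sampling variance
#' for theta_S), plus the haplotype diversity of the sample.
#'
#' @param aln an [aligned_sequence_set()].
#' @param policy site-filter policy, see [filter_sites()].
#' @return Object of class `diversity_summary`: named list with `n`, `S`,
#'   `k_bar` (mean pairwise differences), `theta_pi`, `sd_theta_pi`,
#'   `theta_S`, `sd_theta_S`, `Hd`, `sd_Hd`, `effective_length`, `policy`.
#' @export
nucleotide_diversity <- function(aln, policy = "exclude-gap-columns") {
  stopifnot(inherits(aln, "aln_set"))
  fs <- filter_sites(aln, policy)
  n <- nrow(fs$matrix)
  if (n < 2) stop("need at least two sequences", call. = FALSE)
  L <- fs$effective_length
  if (L == 0) stop("zero effective length after site filtering",
                   call. = FALSE)
  seg <- vapply(seq_len(L), function(j) {
    col <- fs$matrix[, j]
    col <- col[col != "-" & col != "N"]
    length(unique(col)) > 1L
  }, logical(1L))
  S <- sum(seg)
  d <- pairwise_diffs(fs$matrix, policy)
  k_bar <- mean(d[upper.tri(d)])
  pi_site <- k_bar / L
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  theta_S <- S / (a1 * L)
  # Nei (1987) eq. 10.7: sampling variance of per-site pi
  v_pi <- (n + 1) / (3 * (n - 1)) * pi_site / L +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi_site^2
  # Var(S) = a1*theta*L + a2*(theta*L)^2, theta estimated by theta_S
  v_S <- a1 * theta_S * L + a2 * (theta_S * L)^2
  sd_theta_S <- sqrt(v_S) / (a1 * L)
  ht <- collapse_haplotypes(aln, policy)
  hd <- haplotype_diversity(rowSums(ht$counts))
  structure(
    list(n = n, S = S, k_bar = k_bar,
         theta_pi = pi_site, sd_theta_pi = sqrt(v_pi),
         theta_S = theta_S, sd_theta_S = sd_theta_S,
         Hd = unname(hd["Hd"]), sd_Hd = unname(hd["sd"]),
         effective_length = L, policy = policy),
    class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf(
    "n = %d, S = %d, k_bar = %.4f (effective length %d, %s)\n",
    x$n, x$S, x$k_bar, x$effective_length, x$policy))
  cat(sprintf("Hd       = %.4f (sd %.4f)\n", x$Hd, x$sd_Hd))
  cat(sprintf("theta_pi = %.5f (sd %.5f) per site\n",
              x$theta_pi, x$sd_theta_pi))
  cat(sprintf("theta_S  = %.5f (sd %.5f) per site\n",
              x$theta_S, x$sd_theta_S))
  invisible(x)
}

#' Mismatch spectrum of pairwise differences
#'
#' Counts of unordered sequence pairs at each pairwise-difference value
#' `0..d_max`, with relative frequencies. The class 0 is always included.
#'
#' @param aln an [aligned_sequence_set()].
#' @param policy site-filter policy.
#' @return Object of class `mismatch_spectrum`: list with `counts` (named
#'   integer vector over difference classes 0..d_max), `freq`, `n`,
#'   `n_pairs`, `k_bar`.
#' @export
mismatch_spectrum <- function(aln, policy = "exclude-gap-columns") {
  stopifnot(inherits(aln, "aln_set"))
  fs <- filter_sites(aln, policy)
  n <- nrow(fs$matrix)
  if (n < 2) stop("need at least two sequences", call. = FALSE)
  d <- pairwise_diffs(fs$matrix, policy)
  dv <- d[upper.tri(d)]
  mismatch_spectrum_from_pairs(dv, n)
}

# build the spectrum object from a vector of pairwise differences
mismatch_spectrum_from_pairs <- function(dv, n) {
  dmax <- max(dv)
  counts <- tabulate(dv + 1L, nbins = dmax + 1L)
  names(counts) <- 0:dmax
  structure(
    list(counts = counts, freq = counts / sum(counts),
         n = n, n_pairs = length(dv), k_bar = mean(dv)),
    class = "mismatch_spectrum")
}

#' @export
print.mismatch_spectrum <- function(x, ...) {
  cat("Mismatch spectrum over", x$n_pairs, "pairs (n =", x$n,
      "), mean =", round(x$k_bar, 4), "\n")
  print(x$counts)
  invisible(x)
}

#' Minimum spanning network of haplotypes
#'
#' Builds a minimum spanning tree on pairwise Hamming distances between
#' haplotype representative sequences (Kruskal's algorithm) and additionally
#' records alternative edges: non-tree edges whose weight equals the largest
#' weight on the tree path between their endpoints, the conventional
#' minimum-spanning-network extension.
#'
#' @param ht a `haplotype_table` with representative sequences.
#' @return Object of class `haplotype_network`: list with `nodes` (data frame
#'   id/frequency), `edges` (data frame from/to/steps/alternative).
#' @export
build_haplotype_network <- function(ht) {
  stopifnot(inherits(ht, "haplotype_table"))
  if (is.null(ht$representative))
    stop("haplotype table carries no representative sequences", call. = FALSE)
  ids <- ht$haplotype_ids
  H <- length(ids)
  freq <- rowSums(ht$counts)
  nodes <- data.frame(id = ids, frequency = as.integer(freq))
  if (H == 1L) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = character(),
                                             to = character(),
                                             steps = integer(),
                                             alternative = logical())),
                     class = "haplotype_network"))
  }
  m <- do.call(rbind, strsplit(unname(ht$representative[ids]), ""))
  d <- pairwise_diffs(m)
  # Kruskal MST with union-find
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  ord <- order(w, pairs[, 1L], pairs[, 2L])
  parent <- seq_len(H)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  tree <- matrix(0L, 0L, 2L)
  steps <- integer()
  for (e in ord) {
    i <- pairs[e, 1L]; j <- pairs[e, 2L]
    ri <- findp(i); rj <- findp(j)
    if (ri != rj) {
      parent[ri] <- rj
      tree <- rbind(tree, c(i, j))
      steps <- c(steps, w[e])
    }
  }
  # alternative edges: equal-weight detours (weight == max edge on tree path)
  adj <- lapply(seq_len(H), function(i) integer())
  ew <- list()
  for (r in seq_len(nrow(tree))) {
    i <- tree[r, 1L]; j <- tree[r, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    ew[[paste(min(i, j), max(i, j))]] <- steps[r]
  }
  path_max <- function(a, b) {
    # DFS from a to b returning max edge weight on the unique tree path
    seen <- rep(FALSE, H)
    rec <- function(u, target, mx) {
      if (u == target) return(mx)
      seen[u] <<- TRUE
      for (v in adj[[u]]) if (!seen[v]) {
        res <- rec(v, target,
                   max(mx, ew[[paste(min(u, v), max(u, v))]]))
        if (!is.na(res)) return(res)
      }
      NA_integer_
    }
    rec(a, b, 0L)
  }
  alt <- matrix(0L, 0L, 2L); altw <- integer()
  in_tree <- paste(pmin(tree[, 1L], tree[, 2L]),
                   pmax(tree[, 1L], tree[, 2L]))
  for (e in seq_along(w)) {
    i <- pairs[e, 1L]; j <- pairs[e, 2L]
    key <- paste(min(i, j), max(i, j))
    if (key %in% in_tree) next
    if (w[e] == path_max(i, j)) {
      alt <- rbind(alt, c(i, j)); altw <- c(altw, w[e])
    }
  }
  edges <- data.frame(
    from = ids[c(tree[, 1L], alt[, 1L])],
    to = ids[c(tree[, 2L], alt[, 2L])],
    steps = c(steps, altw),
    alternative = c(rep(FALSE, length(steps)), rep(TRUE, length(altw))))
  structure(list(nodes = nodes, edges = edges), class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("Haplotype network:", nrow(x$nodes), "haplotypes,",
      sum(!x$edges$alternative), "spanning edges (total",
      sum(x$edges$steps[!x$edges$alternative]), "steps),",
      sum(x$edges$alternative), "alternative edges\n")
  invisible(x)
}

#' Write a haplotype network as an edge-list TSV
#' @param net a `haplotype_network`.
#' @param path output TSV path (haplotype_a, haplotype_b, steps,
#'   alternative).
#' @return `path`, invisibly.
#' @export
write_haplotype_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
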