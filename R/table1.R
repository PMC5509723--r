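#' Published haplotype-count table for the banana wild relative survey
#'
#' The eight-population haplotype composition of the Cu/Zn SOD2
#' second-intron survey of *Musa basjoo* var. *formosana* (92 sequences, 16
#' haplotypes), as printed in the source study's descriptive table, for use
#' as a reference input. The printed per-population summary statistics
#' (sample size, haplotype diversity with sd, and the two per-site
#' nucleotide diversity estimates) are attached as the
#' `published_summary` attribute.
#'
#' @return A `haplotype_table` (16 haplotypes x 8 populations) with
#'   attribute `published_summary`: data frame with columns `population`,
#'   `n`, `Hd`, `sd_Hd`, `theta_pi`, `theta_S`.
#' @export
make_table1_fixture <- function() {
  haps <- c("I", "Ia", "Ib", "Ic", "Id", "Ie", "If", "Ig", "Ih", "Ii",
            "Ij", "II", "IIa", "IIb", "IIc", "IId")
  pops <- c("Beishi", "Guanhu", "Sandimen", "Shanmai", "Shitou", "Shouka",
            "Wufeng", "Wulai")
  cnt <- matrix(0L, length(haps), length(pops),
                dimnames = list(haps, pops))
  cnt[c("I", "Id", "IIc", "IId"), "Beishi"] <- c(6L, 2L, 2L, 2L)
  cnt[c("I", "Ig", "IIb"), "Guanhu"] <- c(8L, 2L, 2L)
  cnt["I", "Sandimen"] <- 12L
  cnt[c("I", "Ic", "Ij", "II"), "Shanmai"] <- c(4L, 2L, 2L, 2L)
  cnt[c("I", "Ia", "Ib", "Ih", "II"), "Shitou"] <- c(4L, 2L, 2L, 2L, 2L)
  cnt[c("I", "II"), "Shouka"] <- c(9L, 3L)
  cnt[c("I", "Ie", "If", "Ii", "IIa"), "Wufeng"] <- c(4L, 1L, 1L, 2L, 2L)
  cnt[c("I", "II"), "Wulai"] <- c(8L, 4L)
  ht <- haplotype_table(cnt)
  attr(ht, "published_summary") <- data.frame(
    population = pops,
    n = c(12L, 12L, 12L, 10L, 12L, 12L, 10L, 12L),
    Hd = c(0.727, 0.545, 0, 0.800, 0.848, 0.409, 0.822, 0.485),
    sd_Hd = c(0.109, 0.144, 0, 0.089, 0.067, 0.133, 0.097, 0.106),
    theta_pi = c(0.00173, 0.00096, 0, 0.00141, 0.00144, 0.00097,
                 0.00157, 0.00115),
    theta_S = c(0.00157, 0.00105, 0, 0.00140, 0.00157, 0.00079,
                0.00168, 0.00079))
  ht
}

#' Published outlier and association flags for the AFLP candidate loci
#'
#' The printed decision table of the source study's selection analysis:
#' which of the twelve candidate AFLP loci each genome-scan method flagged
#' (envelope-based scan and posterior-odds scan) and which showed
#' significant environmental associations, for use as reference input to
#' [call_adaptive_loci()].
#'
#' @return List with `fdist` (named logical), `bayes` (named logical, the
#'   published log10 posterior odds as attribute `log10_PO`), and `assoc`
#'   (data frame `locus`, `variable`, `pseudo_r2`, `p`, `significant`).
#' @export
make_table3_fixture <- function() {
  loci <- c("P1_17", "P1_19", "P2_15", "P3_23", "P3_24", "P4_35",
            "P6_12", "P6_17", "P6_25", "P6_30", "P12_29", "P12_49")
  fdist <- stats::setNames(
    loci %in% c("P1_17", "P3_23", "P3_24", "P6_12", "P6_17", "P12_49"),
    loci)
  bayes <- stats::setNames(
    loci %in% c("P3_23", "P3_24", "P6_12", "P6_17", "P6_25"), loci)
  attr(bayes, "log10_PO") <- stats::setNames(
    c(NA, NA, NA, 4.699, 4.398, NA, 1.558, 3, 1.889, NA, NA, NA), loci)
  assoc <- data.frame(
    locus = c("P1_17", "P1_17", "P1_19", "P2_15", "P2_15", "P3_23",
              "P3_24", "P3_24", "P4_35", "P6_12", "P6_30", "P12_29"),
    variable = c("TMI", "wet_days", "BIO1", "TMI", "wet_days", "NDVI",
                 "BIO12", "NDVI", "soil_pH", "BIO1", "WS_mean", "BIO1"),
    pseudo_r2 = c(0.251, 0.106, NA, 0.266, 0.326, 0.115,
                  0.094, 0.105, 0.241, 0.101, 0.362, 0.135),
    p = c(1e-4, 0.0025, 0.00363, 0.0021, 0.0024, 0.0056,
          0.0086, 0.0090, 0.0053, 0.0037, 0.0064, 0.0049),
    significant = TRUE)
  list(fdist = fdist, bayes = bayes, assoc = assoc)
}
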