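# small builders shared across test files

toy_alignment <- function(seqs, pops = NULL, ids = NULL) {
  n <- length(seqs)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  if (is.null(pops)) pops <- rep("p1", n)
  aligned_sequence_set(ids, seqs, stats::setNames(pops, ids))
}

# the two-segregating-site alignment used in several worked examples:
# four sequences, two biallelic sites on a 100 bp background, sequence 4
# carries both derived alleles
two_site_alignment <- function() {
  bg <- strrep("A", 98)
  toy_alignment(c(paste0("CC", bg), paste0("CC", bg),
                  paste0("CC", bg), paste0("TT", bg)))
}

toy_markers <- function(calls, pops) {
  if (is.null(rownames(calls))) rownames(calls) <- paste0("i", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- paste0("L", seq_len(ncol(calls)))
  marker_matrix(calls, stats::setNames(pops, rownames(calls)))
}
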