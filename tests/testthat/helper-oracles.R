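# Independent brute-force oracles used to cross-check the implementation.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Expand a degenerate recognition sequence into every literal word.
expand_degenerate <- function(recognition) {
  sets <- IUPAC_SETS[strsplit(recognition, "")[[1]]]
  words <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(words[, rev(seq_along(sets)), drop = FALSE], 1, paste, collapse = "")
}

# Brute-force cut scan: position-by-position literal comparison against
# every expansion of the recognition sequence (overlaps included; transcript
# N matches nothing because N is not a literal expansion letter).
oracle_cut_positions <- function(sequence, recognition, cut_offset) {
  sequence <- toupper(sequence)
  words <- expand_degenerate(recognition)
  w <- nchar(recognition)
  n <- nchar(sequence)
  if (n < w) return(integer(0))
  hits <- integer(0)
  for (p in seq_len(n - w + 1)) {
    if (substr(sequence, p, p + w - 1) %in% words) hits <- c(hits, p)
  }
  sort(hits - 1L + cut_offset)
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Full-PCR oracle: rebuild the literal amplicon from the printed primer
# geometry (BstYI primer extends 11 nt beyond the 5' cut, MseI primer 15 nt
# beyond the 3' cut) and test whether both full selective primers sit at the
# amplicon ends.
oracle_matches_primer <- function(fragment_seq, bst_variant, bst_sel, mse_sel) {
  amplicon <- paste0("GACTGCGTAGT", fragment_seq,
                     oracle_revcomp("GATGAGTCCTGAGTA"))
  bst_primer <- paste0("GACTGCGTAGTGATC", bst_variant, bst_sel)
  mse_primer <- paste0("GATGAGTCCTGAGTAA", mse_sel)
  startsWith(amplicon, bst_primer) &&
    endsWith(amplicon, oracle_revcomp(mse_primer))
}

# Brute-force DMR enumeration: every maximal chain of differential cytosines
# whose consecutive gaps stay within max_gap, kept when it has >= min_count
# members.
oracle_dmrs <- function(records, min_diff, min_count, max_gap) {
  diff <- records$pct_b - records$pct_a
  dpos <- records$pos[abs(diff) >= min_diff]
  if (length(dpos) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  out <- list()
  i <- 1
  while (i <= length(dpos)) {
    j <- i
    while (j < length(dpos) && dpos[j + 1] - dpos[j] <= max_gap) j <- j + 1
    if (j - i + 1 >= min_count) {
      out[[length(out) + 1]] <- data.frame(start = dpos[i], end = dpos[j])
    }
    i <- j + 1
  }
  if (length(out) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  do.call(rbind, out)
}

random_sequence <- function(n, with_n = FALSE) {
  alphabet <- c("A", "C", "G", "T")
  if (with_n) alphabet <- c(alphabet, "N")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

as_transcript <- function(sequence, id = "tx.1") {
  tibble::tibble(id = id, gene_id = derive_gene_id(id), sequence = sequence)
}
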