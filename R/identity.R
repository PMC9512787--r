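#' Pairwise sequence identity
#'
#' Global (Needleman-Wunsch) alignment of two amino-acid sequences with a
#' BLOSUM62 substitution matrix and affine gap penalties, followed by
#' percent identity computed as identical aligned positions over aligned
#' columns, excluding terminal-gap columns (overhanging ends are not
#' counted against identity). Microtubule-binding calponin-homology
#' domains typically share only 10-20% identity by this measure while
#' remaining structurally near-identical, which is why structure rather
#' than sequence drives their comparison.
#'
#' @param seq_a,seq_b amino-acid strings (standard 20-letter alphabet)
#' @param gap_open,gap_extend affine gap penalties (positive costs)
#' @return a one-row tibble: `identity` (percent, 0-100), `n_match`,
#'   `n_columns` (aligned columns in the denominator), `score`,
#'   `aligned_a`, `aligned_b`
#' @export
pairwise_identity <- function(seq_a, seq_b, gap_open = 10, gap_extend = 1) {
  check_aa <- function(s, nm) {
    if (!is.character(s) || length(s) != 1 || nchar(s) == 0) {
      stop(nm, " must be a non-empty string", call. = FALSE)
    }
    bad <- setdiff(strsplit(toupper(s), "")[[1]],
                   strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    if (length(bad) > 0) {
      stop(nm, " contains non-amino-acid characters: ",
           paste(unique(bad), collapse = ""), call. = FALSE)
    }
    toupper(s)
  }
  seq_a <- check_aa(seq_a, "seq_a")
  seq_b <- check_aa(seq_b, "seq_b")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend
  )
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ident_from_alignment(a, b, score = Biostrings::score(aln))
}

# identity bookkeeping shared with the test oracle: given two aligned
# character vectors, drop terminal-gap columns and count matches
ident_from_alignment <- function(a, b, score = NA_real_) {
  n <- length(a)
  gap_a <- a == "-"
  gap_b <- b == "-"
  lead <- function(g) if (g[1]) seq_len(rle(g)$lengths[1]) else integer(0)
  terminal <- unique(c(lead(gap_a), lead(gap_b),
                       n + 1 - lead(rev(gap_a)), n + 1 - lead(rev(gap_b))))
  keep <- setdiff(seq_len(n), terminal)
  n_match <- sum(a[keep] == b[keep] & a[keep] != "-")
  n_col <- length(keep)
  tibble::tibble(
    identity = if (n_col > 0) 100 * n_match / n_col else NA_real_,
    n_match = n_match, n_columns = n_col, score = score,
    aligned_a = paste(a, collapse = ""), aligned_b = paste(b, collapse = "")
  )
}
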