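# Pairwise global alignment utilities shared by the detector, the age module
# and the library clusterer. Scoring follows the package defaults
# (match +2, mismatch -3, gap open 5, gap extend 2, penalties positive);
# N never scores as a match.

ltr_submat <- function(match = 2, mismatch = -3) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m)[1:4] <- match
  m["N", "N"] <- mismatch  # N is never a match
  m
}

#' Global pairwise alignment of two DNA sequences
#'
#' End-to-end (Needleman-Wunsch style) alignment with affine gap penalties,
#' delegated to [Biostrings::pairwiseAlignment()]. Identity is defined as
#' matching columns divided by total alignment columns, end gaps included;
#' `N` never counts as a match.
#'
#' @param a,b Character scalars or `DNAString`s.
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Positive gap penalties.
#' @return A list with `aligned_a`, `aligned_b` (gapped strings), `score`,
#'   `matches`, `columns`, `identity`.
#' @export
align_global <- function(a, b, match = 2, mismatch = -3,
                         gap_open = 5, gap_extend = 2) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0 || nchar(b) == 0) abort("align_global: empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = ltr_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global"
  )
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(pa, "", fixed = TRUE)[[1]]
  cb <- strsplit(pb, "", fixed = TRUE)[[1]]
  matches <- sum(ca == cb & ca != "-" & ca != "N")
  list(
    aligned_a = pa, aligned_b = pb,
    score = Biostrings::score(aln),
    matches = matches, columns = length(ca),
    identity = matches / length(ca)
  )
}

#' Alignment identity between two sequences
#'
#' Convenience wrapper: global alignment identity (matches / columns,
#' gaps counted as columns).
#'
#' @inheritParams align_global
#' @return A fraction in \[0, 1\].
#' @export
alignment_identity <- function(a, b, match = 2, mismatch = -3,
                               gap_open = 5, gap_extend = 2) {
  align_global(a, b, match, mismatch, gap_open, gap_extend)$identity
}

# -- small sequence helpers -------------------------------------------------

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

seq_chars <- function(x) strsplit(as.character(x), "", fixed = TRUE)[[1]]
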