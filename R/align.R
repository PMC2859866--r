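# Pairwise alignment wrappers (Biostrings) under the +1/-3 scoring used
# throughout: local alignment for marker homology searches, global alignment
# for backbone fragments. Gap penalties (open 5, extend 1) are not stated by
# the upstream protocol and are package defaults.

.dna_submat <- function(match = 1, mismatch = -3) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- mismatch
  m[, "N"] <- mismatch
  m
}

#' Best local alignment of two sequences
#'
#' Smith-Waterman local alignment under match/mismatch scoring with affine
#' gaps; the E-value uses the ungapped Karlin-Altschul statistics of
#' [karlin_parameters()] with search space `nchar(a) * nchar(b)`.
#'
#' @param a,b nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend scoring scheme.
#' @return List with `score`, `aligned_length` (alignment columns),
#'   `identity` (fraction), `evalue` and `log10_evalue`.
#' @export
local_align <- function(a, b, match = 1, mismatch = -3, gap_open = 5,
                        gap_extend = 1) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = .dna_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend)
  aln_a <- as.character(Biostrings::alignedPattern(pa))
  width <- nchar(aln_a)
  kp <- karlin_parameters(match, mismatch)
  l10 <- log10_evalue(Biostrings::score(pa), nchar(a), nchar(b), kp)
  list(score = Biostrings::score(pa), aligned_length = width,
       identity = Biostrings::pid(pa) / 100,
       evalue = 10^l10, log10_evalue = l10)
}

#' Global alignment of two sequences
#'
#' Needleman-Wunsch with the same scoring; returns the two gapped strings.
#'
#' @inheritParams local_align
#' @export
global_align <- function(a, b, match = 1, mismatch = -3, gap_open = 5,
                         gap_extend = 1) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = .dna_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend)
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

# score-only local alignment of one query against many subjects
.align_scores <- function(query, subjects, match = 1, mismatch = -3,
                          gap_open = 5, gap_extend = 1) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(subjects), Biostrings::DNAString(query),
    type = "local", substitutionMatrix = .dna_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
}
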