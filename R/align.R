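#' Global pairwise identity and coverage between two proteins
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 10, gap extend 0.5)
#' of two amino-acid strings. Identity is matches divided by alignment columns
#' (end gaps included); coverage is the number of columns where both sequences
#' carry a residue, divided by the length of the shorter sequence. These are
#' the quantities the greedy clusterer tests against its identity/coverage
#' contract.
#'
#' @param a,b Amino-acid strings (character or `AAString`). U and O are mapped
#'   to C and K for scoring, since the substitution matrix lacks them.
#' @return A list with elements `identity` and `coverage`, both in `[0, 1]`.
#' @export
#' @examples
#' pairwise_identity("MKVLAT", "MKVLAT")$identity
pairwise_identity <- function(a, b) {
  a <- chartr("UO", "CK", toupper(as.character(a)))
  b <- chartr("UO", "CK", toupper(as.character(b)))
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  ncols <- nchar(as.character(Biostrings::pattern(aln)))
  nmat <- Biostrings::nmatch(aln)
  nmis <- Biostrings::nmismatch(aln)
  list(identity = nmat / ncols,
       coverage = (nmat + nmis) / min(nchar(a), nchar(b)))
}
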