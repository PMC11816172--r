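#' Numerator relationship matrix from a pedigree (tabular method)
#'
#' Builds the additive (numerator) relationship matrix A over the
#' topologically ordered pedigree by the tabular recursion: for animal i
#' with parents s and d, `A[i,i] = 1 + 0.5 * A[s,d]` (inbreeding from the
#' parental relationship) and `A[i,j] = 0.5 * (A[j,s] + A[j,d])`; a missing
#' parent contributes 0.
#'
#' @param pedigree a [pedigree_table] (or coercible data.frame with columns
#'   animal, sire, dam).
#' @return symmetric matrix with animal ids as dimnames, class
#'   `relationship_matrix`.
#' @export
build_A <- function(pedigree) {
  if (!inherits(pedigree, "pedigree_table")) {
    pedigree <- pedigree_table(pedigree$animal, pedigree$sire, pedigree$dam)
  }
  n <- nrow(pedigree)
  idx <- stats::setNames(seq_len(n), pedigree$animal)
  si <- ifelse(is.na(pedigree$sire), 0L, idx[pedigree$sire])
  di <- ifelse(is.na(pedigree$dam),  0L, idx[pedigree$dam])
  A <- matrix(0, n, n, dimnames = list(pedigree$animal, pedigree$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- 0.5 * ((if (s > 0L) A[j, s] else 0) + (if (d > 0L) A[j, d] else 0))
      A[j, i] <- aj
      A[i, j] <- aj
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  class(A) <- c("relationship_matrix", class(A))
  A
}
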