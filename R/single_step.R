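#' Single-step H-inverse
#'
#' Combines pedigree and genomic information into the inverse of the
#' single-step relationship matrix H:
#' \deqn{H^{-1} = A^{-1} + \begin{pmatrix} 0 & 0 \\
#'   0 & \tau G^{-1} - \omega A_{22}^{-1} \end{pmatrix}}
#' with the nonzero block on the genotyped rows/columns.  With the defaults
#' `tau = omega = 1` this is the original single-step formulation: G simply
#' replaces A22 inside A.  When the genotyped set is empty, or when
#' `G == A22`, the correction vanishes and `H^{-1} == A^{-1}`.
#'
#' @param Ainv `relationship_matrix` of kind `"A_inverse"` over the full
#'   pedigree.
#' @param G `relationship_matrix` of kind `"G"` over the genotyped animals
#'   (blended so it is invertible).
#' @param A22 `relationship_matrix` of kind `"A22"`, same id order as `G`.
#' @param genotyped_ids Ids of the genotyped animals; must all be in
#'   `Ainv$ids` and match the order of `G`/`A22`.
#' @param tau,omega Block weights, defaults 1.
#' @return `relationship_matrix` of kind `"H_inverse"` (sparse storage:
#'   sparse pedigree part plus one dense genotyped block).
#' @export
build_h_inverse <- function(Ainv, G, A22, genotyped_ids, tau = 1,
                            omega = 1) {
  stopifnot(inherits(Ainv, "relationship_matrix"),
            Ainv$kind == "A_inverse")
  genotyped_ids <- as.character(genotyped_ids)
  H <- methods::as(methods::as(Ainv$matrix, "generalMatrix"),
                   "CsparseMatrix")
  if (length(genotyped_ids) == 0L) {
    return(relationship_matrix(Matrix::forceSymmetric(H), Ainv$ids,
                               kind = "H_inverse"))
  }
  stopifnot(inherits(G, "relationship_matrix"), G$kind == "G",
            inherits(A22, "relationship_matrix"), A22$kind == "A22")
  missing <- setdiff(genotyped_ids, Ainv$ids)
  if (length(missing)) {
    stop("genotyped animals absent from pedigree (add them as pedigree ",
         "records first): ", paste(utils::head(missing, 5L),
                                   collapse = ", "))
  }
  if (!identical(G$ids, genotyped_ids) ||
      !identical(A22$ids, genotyped_ids)) {
    stop("G and A22 must be indexed by genotyped_ids in identical order")
  }
  Ginv <- invert_relationship(G)
  A22inv <- invert_relationship(A22)
  corr <- tau * as.matrix(Ginv$matrix) - omega * as.matrix(A22inv$matrix)
  idx <- match(genotyped_ids, Ainv$ids)
  H[idx, idx] <- H[idx, idx] + corr
  H <- Matrix::forceSymmetric((H + Matrix::t(H)) / 2)
  relationship_matrix(H, Ainv$ids, kind = "H_inverse")
}
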