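#' Relationship matrix container
#'
#' A symmetric animal-indexed kinship matrix together with the ordered animal
#' ids its rows refer to and a tag saying which kinship it is (`A`,
#' `A_inverse`, `A22`, `A22_inverse`, `G`, `G_inverse`, `H_inverse`).  The
#' matrix may be a base dense matrix or a sparse `Matrix`; dimnames are set
#' to the ids so joins are always by id, never by position.
#'
#' @param matrix Symmetric numeric matrix (base or `Matrix`).
#' @param ids Character vector of animal ids, one per row.
#' @param kind One of `"A"`, `"A_inverse"`, `"A22"`, `"A22_inverse"`, `"G"`,
#'   `"G_inverse"`, `"H_inverse"`.
#' @return Object of class `relationship_matrix`: list with elements
#'   `matrix`, `ids`, `kind`.
#' @export
relationship_matrix <- function(matrix, ids,
                                kind = c("A", "A_inverse", "A22",
                                         "A22_inverse", "G", "G_inverse",
                                         "H_inverse")) {
  kind <- match.arg(kind)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate ids in relationship matrix")
  if (nrow(matrix) != length(ids) || ncol(matrix) != length(ids)) {
    stop("matrix dimension does not match id list")
  }
  sym <- if (methods::is(matrix, "symmetricMatrix")) TRUE
  else if (methods::is(matrix, "Matrix")) {
    max(abs(matrix - Matrix::t(matrix))) <= 1e-10
  } else isSymmetric(matrix, tol = 1e-10, check.attributes = FALSE)
  if (!sym) stop("relationship matrix is not symmetric (tolerance 1e-10)")
  dimnames(matrix) <- list(ids, ids)
  structure(list(matrix = matrix, ids = ids, kind = kind),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("<relationship_matrix kind=%s, %d animals, %s storage>\n",
              x$kind, length(x$ids),
              if (methods::is(x$matrix, "sparseMatrix")) "sparse" else
                "dense"))
  invisible(x)
}

#' Dense base-matrix view of a relationship matrix
#' @param x A `relationship_matrix`.
#' @return Base dense matrix with id dimnames.
#' @export
as_dense <- function(x) {
  stopifnot(inherits(x, "relationship_matrix"))
  as.matrix(x$matrix)
}

#' Extract the genotyped block A22 of a numerator relationship matrix
#'
#' Returns the principal submatrix of `A` restricted to the genotyped
#' animals, in exactly the order of `genotyped_ids` (which must match the
#' row order of the genotype set so that A22 and G are conformable).
#'
#' @param A `relationship_matrix` of kind `"A"`.
#' @param genotyped_ids Character vector of genotyped animal ids, a subset of
#'   `A$ids`.
#' @return `relationship_matrix` of kind `"A22"`.
#' @export
extract_a22 <- function(A, genotyped_ids) {
  stopifnot(inherits(A, "relationship_matrix"), A$kind == "A")
  genotyped_ids <- as.character(genotyped_ids)
  missing <- setdiff(genotyped_ids, A$ids)
  if (length(missing)) {
    stop("genotyped ids absent from A: ", paste(missing, collapse = ", "))
  }
  idx <- match(genotyped_ids, A$ids)
  relationship_matrix(as.matrix(A$matrix)[idx, idx, drop = FALSE],
                      genotyped_ids, kind = "A22")
}

#' Export / import a relationship matrix as CSV
#'
#' The CSV carries the ids as header row and first column so matrices can be
#' cross-checked against other tools.
#' @param x `relationship_matrix`.
#' @param path Output file.
#' @export
export_matrix <- function(x, path) {
  stopifnot(inherits(x, "relationship_matrix"))
  m <- as.matrix(x$matrix)
  df <- data.frame(id = x$ids, m, check.names = FALSE)
  colnames(df) <- c("id", x$ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_matrix
#' @param kind Kind tag to attach on import.
#' @export
import_matrix <- function(path, kind = "A") {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  # symmetrise away CSV round-trip noise
  m <- (m + t(m)) / 2
  relationship_matrix(m, ids, kind = kind)
}
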