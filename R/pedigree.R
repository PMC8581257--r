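#' Pedigree table
#'
#' A validated pedigree: one row per animal with its sire and dam, missing
#' parents as `NA`, rows in a topological order (parents always before
#' offspring).  Construction normalises the common unknown-parent codes
#' (`"0"`, `""`, `"NA"`, `"."`), inserts implicit founder rows for parents
#' that have no row of their own, rejects duplicate animal rows and detects
#' ancestry cycles.
#'
#' @param df Data frame whose first three columns are animal, sire, dam
#'   (further columns are ignored).
#' @return Object of class `pedigree_table`: a data.frame with character
#'   columns `animal`, `sire`, `dam` in topological order.
#' @export
as_pedigree <- function(df) {
  stopifnot(is.data.frame(df), ncol(df) >= 3L)
  animal <- normalize_id(df[[1L]])
  sire <- normalize_id(df[[2L]])
  dam <- normalize_id(df[[3L]])
  if (anyNA(animal)) stop("animal id missing in pedigree row(s)")
  if (anyDuplicated(animal)) {
    stop("duplicate animal row(s) in pedigree: ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  parents <- unique(c(sire, dam))
  implicit <- setdiff(parents[!is.na(parents)], animal)
  if (length(implicit)) {
    hb_log("pedigree: inserting %d implicit founder(s)", length(implicit))
    animal <- c(implicit, animal)
    sire <- c(rep(NA_character_, length(implicit)), sire)
    dam <- c(rep(NA_character_, length(implicit)), dam)
  }
  ord <- topo_order(animal, sire, dam)
  structure(data.frame(animal = animal[ord], sire = sire[ord],
                       dam = dam[ord], stringsAsFactors = FALSE),
            class = c("pedigree_table", "data.frame"))
}

normalize_id <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("0", "", "NA", "na", ".")] <- NA_character_
  x
}

# Kahn topological sort over the parent -> offspring DAG; errors naming the
# animals involved when a cycle (an animal being its own ancestor) exists.
topo_order <- function(animal, sire, dam) {
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])
  if (any(si == idx | di == idx)) {
    bad <- animal[si == idx | di == idx]
    stop("pedigree cycle detected involving: ", paste(bad, collapse = ", "))
  }
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in idx) {
    if (si[i] > 0L) children[[si[i]]] <- c(children[[si[i]]], i)
    if (di[i] > 0L) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  queue <- idx[indeg == 0L]
  out <- integer(0)
  while (length(queue)) {
    i <- queue[[1L]]
    queue <- queue[-1L]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    stop("pedigree cycle detected involving: ",
         paste(animal[setdiff(idx, out)], collapse = ", "))
  }
  out
}

#' Read a pedigree CSV
#'
#' Expects a header `animal,sire,dam`; `"0"`, empty or `"NA"` mark unknown
#' parents.  See [as_pedigree()] for validation rules.
#' @param path CSV file path.
#' @return A `pedigree_table`.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  as_pedigree(df)
}

#' @rdname read_pedigree
#' @param ped A `pedigree_table`.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree_table"))
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# parent column indices (0 = unknown) for a sorted pedigree
parent_index <- function(ped) {
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$animal
  list(s = ifelse(is.na(ped$sire), 0L, idx[ped$sire]),
       d = ifelse(is.na(ped$dam), 0L, idx[ped$dam]))
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' recursion in topological order: `a(i,i) = 1 + 0.5 a(s,d)` and, for an
#' older animal j, `a(i,j) = 0.5 (a(j,s) + a(j,d))`, where an unknown parent
#' contributes 0 (unrelated, non-inbred phantom).
#'
#' @param ped A `pedigree_table`.
#' @return `relationship_matrix` of kind `"A"`, ids in pedigree order.
#' @export
build_a_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree_table"))
  n <- nrow(ped)
  pi <- parent_index(ped)
  s <- pi$s; d <- pi$d
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      rel <- 0.5 * ((if (s[i] > 0L) A[prev, s[i]] else 0) +
                    (if (d[i] > 0L) A[prev, d[i]] else 0))
      A[prev, i] <- rel
      A[i, prev] <- rel
    }
    A[i, i] <- 1 + (if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0)
  }
  relationship_matrix(A, ped$animal, kind = "A")
}

#' Inbreeding coefficients
#'
#' `F = diag(A) - 1` from the tabular A.
#' @param ped A `pedigree_table`.
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  A <- build_a_matrix(ped)
  stats::setNames(diag(as.matrix(A$matrix)) - 1, ped$animal)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: for animal i with Mendelian-sampling
#' variance `m_i = 1 - 0.25 * sum over known parents p of (1 + F_p)`,
#' `alpha = 1/m_i` is added at (i,i), `-alpha/2` between i and each known
#' parent, and `alpha/4` among the known parents.  Inbreeding coefficients
#' come from the tabular A, so the result equals the dense inverse of
#' [build_a_matrix()] to numerical precision.
#'
#' @param ped A `pedigree_table`.
#' @return `relationship_matrix` of kind `"A_inverse"` with sparse storage.
#' @export
build_a_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree_table"))
  n <- nrow(ped)
  pi <- parent_index(ped)
  f <- unname(inbreeding(ped))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  # triplet buffers grown in blocks to avoid O(n^2) appends
  buf_i <- vector("list", n); buf_j <- vector("list", n)
  buf_x <- vector("list", n)
  for (i in seq_len(n)) {
    par <- c(pi$s[i], pi$d[i])
    par <- par[par > 0L]
    m <- 1 - if (length(par)) 0.25 * sum(1 + f[par]) else 0
    a <- 1 / m
    ti <- i; tj <- i; tx <- a
    for (p in par) {
      ti <- c(ti, i, p); tj <- c(tj, p, i); tx <- c(tx, -a / 2, -a / 2)
    }
    if (length(par)) {
      pp <- expand.grid(par, par)
      ti <- c(ti, pp[[1L]]); tj <- c(tj, pp[[2L]])
      tx <- c(tx, rep(a / 4, nrow(pp)))
    }
    buf_i[[i]] <- ti; buf_j[[i]] <- tj; buf_x[[i]] <- tx
  }
  Ainv <- Matrix::sparseMatrix(i = unlist(buf_i), j = unlist(buf_j),
                               x = unlist(buf_x), dims = c(n, n),
                               symmetric = FALSE)
  Ainv <- Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2)
  relationship_matrix(Ainv, ped$animal, kind = "A_inverse")
}
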