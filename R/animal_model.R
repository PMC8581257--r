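#' Design matrices for the repeatability animal model
#'
#' The model for a 305-day record is
#' `y = mu + breed + lactation_number + HYS + animal + permanent_env + e`.
#' Fixed effects are reference-level (drop-first) coded with the intercept
#' retained; factors with a single observed level contribute no column.
#' Columns that are linearly dependent after level dropping are removed by
#' pivoted QR with a warning (only estimable functions matter downstream).
#' `Z_a` maps records to *all* animals in `ids` (so unphenotyped animals
#' obtain breeding values through their relationships); `Z_pe` maps records
#' to the phenotyped animals only.
#'
#' @param records A [as_records()] table.
#' @param ids Ordered animal ids of the relationship structure.
#' @return List: `X` (dense), `Z_a`, `Z_pe` (sparse), `y`, `pheno_ids`,
#'   `xlev` (factor levels used, for out-of-sample adjustment),
#'   `coef_names`.
#' @export
build_design <- function(records, ids) {
  stopifnot(inherits(records, "lactation_records"))
  ids <- as.character(ids)
  j <- match(records$animal_id, ids)
  if (anyNA(j)) {
    stop("record animal(s) missing from relationship ids: ",
         paste(utils::head(unique(records$animal_id[is.na(j)]), 5L),
               collapse = ", "))
  }
  fac <- list(breed = factor(records$breed),
              lactation_number = factor(records$lactation_number),
              hys = factor(records$hys))
  use <- vapply(fac, function(f) nlevels(f) >= 2L, logical(1))
  if (any(use)) {
    form <- stats::as.formula(paste("~", paste(names(fac)[use],
                                               collapse = " + ")))
    dat <- as.data.frame(fac[use])
    X <- stats::model.matrix(form, dat)
  } else {
    X <- matrix(1, nrow(records), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    warning("dropping ", length(drop),
            " aliased fixed-effect column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
  }
  n <- nrow(records)
  Z_a <- Matrix::sparseMatrix(i = seq_len(n), j = j, x = 1,
                              dims = c(n, length(ids)))
  pheno_ids <- ids[ids %in% records$animal_id]
  Z_pe <- Matrix::sparseMatrix(i = seq_len(n),
                               j = match(records$animal_id, pheno_ids),
                               x = 1, dims = c(n, length(pheno_ids)))
  list(X = X, Z_a = Z_a, Z_pe = Z_pe, y = records$yield,
       ids = ids, pheno_ids = pheno_ids,
       xlev = lapply(fac[use], levels), coef_names = colnames(X))
}

#' Solve Henderson's mixed-model equations
#'
#' Solves
#' \deqn{\begin{pmatrix}
#'   X'X & X'Z_a & X'Z_p \\
#'   Z_a'X & Z_a'Z_a + \lambda_A K^{-1} & Z_a'Z_p \\
#'   Z_p'X & Z_p'Z_a & Z_p'Z_p + \lambda_{PE} I
#' \end{pmatrix}
#' \begin{pmatrix} \hat b \\ \hat u \\ \hat p \end{pmatrix} =
#' \begin{pmatrix} X'y \\ Z_a'y \\ Z_p'y \end{pmatrix}}
#' by sparse Cholesky with one step of iterative refinement.  `K^{-1}` is
#' the inverse relationship structure and is the *only* thing that differs
#' between pBLUP (`A^{-1}`), GBLUP (`G^{-1}`) and ssGBLUP (`H^{-1}`) — all
#' three run through this identical code path.  When
#' `vc$sigma2_pe == 0` the permanent-environment block is omitted.
#'
#' @param design Output of [build_design()].
#' @param Kinv `relationship_matrix` of an `_inverse` kind whose ids equal
#'   `design$ids`.
#' @param vc [variance_components()] list.
#' @return Object of class `model_solution`: `fixed` (named vector), `ebv`
#'   (named, all animals in `Kinv$ids`), `pe` (named, phenotyped animals; or
#'   `NULL`), `xlev`, `coef_names`, `diagnostics`.
#' @export
solve_mme <- function(design, Kinv, vc) {
  stopifnot(inherits(Kinv, "relationship_matrix"),
            grepl("_inverse$", Kinv$kind))
  if (!identical(as.character(Kinv$ids), design$ids)) {
    stop("Kinv ids do not match design ids")
  }
  X <- Matrix::Matrix(design$X, sparse = TRUE)
  Za <- design$Z_a
  y <- design$y
  K <- methods::as(methods::as(Kinv$matrix, "generalMatrix"),
                   "CsparseMatrix")
  use_pe <- is.finite(vc$lambda_pe) && vc$sigma2_pe > 0
  np <- ncol(X); na <- ncol(Za)
  blocks_top <- cbind(Matrix::crossprod(X), Matrix::crossprod(X, Za))
  blocks_mid <- cbind(Matrix::t(Matrix::crossprod(X, Za)),
                      Matrix::crossprod(Za) + vc$lambda_a * K)
  rhs <- c(as.vector(Matrix::crossprod(X, y)),
           as.vector(Matrix::crossprod(Za, y)))
  if (use_pe) {
    Zp <- design$Z_pe
    rhs <- c(rhs, as.vector(Matrix::crossprod(Zp, y)))
    blocks_top <- cbind(blocks_top, Matrix::crossprod(X, Zp))
    blocks_mid <- cbind(blocks_mid, Matrix::crossprod(Za, Zp))
    blocks_bot <- cbind(Matrix::t(Matrix::crossprod(X, Zp)),
                        Matrix::t(Matrix::crossprod(Za, Zp)),
                        Matrix::crossprod(Zp) +
                          vc$lambda_pe * Matrix::Diagonal(ncol(Zp)))
    LHS <- rbind(blocks_top, blocks_mid, blocks_bot)
  } else {
    LHS <- rbind(blocks_top, blocks_mid)
  }
  LHS <- Matrix::forceSymmetric(methods::as(LHS, "CsparseMatrix"))
  fact <- tryCatch(Matrix::Cholesky(LHS, LDL = FALSE),
                   error = function(e) {
    stop("mixed-model coefficient matrix is not positive definite ",
         "(conditioning: ", conditionMessage(e), ")", call. = FALSE)
  })
  sol <- as.vector(Matrix::solve(fact, rhs))
  # one refinement step keeps the solution near machine precision
  resid <- rhs - as.vector(LHS %*% sol)
  sol <- sol + as.vector(Matrix::solve(fact, resid))
  fixed <- stats::setNames(sol[seq_len(np)], design$coef_names)
  ebv <- stats::setNames(sol[np + seq_len(na)], design$ids)
  pe <- if (use_pe) {
    stats::setNames(sol[np + na + seq_len(length(design$pheno_ids))],
                    design$pheno_ids)
  } else NULL
  structure(list(fixed = fixed, ebv = ebv, pe = pe,
                 xlev = design$xlev, coef_names = design$coef_names,
                 diagnostics = list(
                   n_eq = length(sol),
                   refinement_residual = max(abs(resid)))),
            class = "model_solution")
}

#' @export
print.model_solution <- function(x, ...) {
  cat(sprintf("<model_solution: %d fixed effects, %d breeding values%s>\n",
              length(x$fixed), length(x$ebv),
              if (is.null(x$pe)) "" else
                sprintf(", %d permanent-environment effects",
                        length(x$pe))))
  invisible(x)
}

# fixed-effect fitted value x'b for new records under a fitted solution;
# records with factor levels unseen in training get NA
fixed_fitted <- function(records, solution) {
  n <- nrow(records)
  keep <- rep(TRUE, n)
  dat <- list()
  for (f in names(solution$xlev)) {
    v <- as.character(records[[f]])
    keep <- keep & v %in% solution$xlev[[f]]
    dat[[f]] <- v
  }
  fitted <- rep(NA_real_, n)
  if (any(keep)) {
    if (length(solution$xlev)) {
      dat <- as.data.frame(lapply(dat, `[`, keep),
                           stringsAsFactors = FALSE)
      for (f in names(solution$xlev)) {
        dat[[f]] <- factor(dat[[f]], levels = solution$xlev[[f]])
      }
      form <- stats::as.formula(paste("~", paste(names(solution$xlev),
                                                 collapse = " + ")))
      Xn <- stats::model.matrix(form, dat)
    } else {
      Xn <- matrix(1, sum(keep), 1L,
                   dimnames = list(NULL, "(Intercept)"))
    }
    Xn <- Xn[, solution$coef_names, drop = FALSE]
    fitted[keep] <- as.vector(Xn %*% solution$fixed)
  }
  fitted
}

#' Adjusted phenotypes
#'
#' Subtracts the fitted fixed part from each record
#' (`y* = y - x'b`, including the intercept) and averages the adjusted
#' records per animal.  Records whose fixed-effect levels were not
#' estimated in the fit (e.g. an HYS class seen only in a test set) are
#' excluded with a logged count.
#'
#' @param records A `lactation_records` table.
#' @param solution A `model_solution` (normally fitted on training data).
#' @return Data frame: `animal_id`, `adj_pheno` (mean adjusted record),
#'   `n_records`; attribute `n_dropped` counts excluded records.
#' @export
adjust_phenotypes <- function(records, solution) {
  stopifnot(inherits(records, "lactation_records"),
            inherits(solution, "model_solution"))
  fitted <- fixed_fitted(records, solution)
  drop <- is.na(fitted)
  if (any(drop)) {
    hb_log("adjust: excluded %d record(s) with unestimated fixed levels",
           sum(drop))
  }
  ystar <- records$yield[!drop] - fitted[!drop]
  animal <- records$animal_id[!drop]
  agg <- tapply(ystar, animal, mean)
  cnt <- tapply(ystar, animal, length)
  out <- data.frame(animal_id = names(agg),
                    adj_pheno = as.vector(agg),
                    n_records = as.vector(cnt),
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(drop)
  out
}
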