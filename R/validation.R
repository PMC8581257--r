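#' Threefold lactation-count cross-validation folds
#'
#' Animals are assigned to one of three test sets by how many lactation
#' records they have (1, 2 or 3), regardless of *which* lactation numbers
#' those are: a cow with only its second lactation is in the 1-record fold,
#' a cow with the first and third lactations is in the 2-record fold.  For
#' each fold the training set is every record of the animals *not* in the
#' fold.
#'
#' @param records A [as_records()] table (each animal 1-3 records).
#' @return List of three folds, each a list with `label`, `n` (lactation
#'   count), `test_ids`, `test_rows`, `train_rows` (row indices into
#'   `records`).
#' @export
assign_folds <- function(records) {
  stopifnot(inherits(records, "lactation_records"))
  cnt <- table(records$animal_id)
  lapply(1:3, function(n) {
    test_ids <- names(cnt)[cnt == n]
    test_rows <- which(records$animal_id %in% test_ids)
    list(label = sprintf("%d-record", n), n = n, test_ids = test_ids,
         test_rows = test_rows,
         train_rows = setdiff(seq_len(nrow(records)), test_rows))
  })
}

#' Cross-validation accuracy of prediction
#'
#' Converts the correlation between predicted breeding values and adjusted
#' phenotypes of a test set into an accuracy by dividing by the square root
#' of the heritability of an n-record mean:
#' \deqn{r = \frac{corr}{\sqrt{h^2 / (rep + (1 - rep)/n)}}}
#' where `n` is the number of lactation records of the test-set animals.
#' At `n = 1` the denominator is exactly `h`; the general denominator is
#' `sqrt(n h^2 / (1 + (n-1) rep))`, the classical heritability of the mean
#' of n repeated records.
#'
#' @param correlation Pearson correlation between predicted breeding values
#'   and mean adjusted phenotypes.
#' @param h2 Heritability in (0, 1).
#' @param rep Repeatability, `h2 <= rep < 1`.
#' @param n Number of lactation records in the test set (1, 2 or 3).
#' @return The accuracy `r`.
#' @export
accuracy <- function(correlation, h2, rep, n) {
  if (!(is.numeric(h2) && h2 > 0)) stop("h2 must be positive")
  if (h2 > rep) stop("h2 cannot exceed repeatability")
  stopifnot(n %in% 1:3)
  correlation / sqrt(h2 / (rep + (1 - rep) / n))
}

#' Dispersion-bias slope
#'
#' Ordinary least-squares slope of the adjusted phenotypes (response) on
#' the predicted breeding values (predictor).  A slope of 1 indicates no
#' dispersion bias; below 1, over-dispersed (overestimated) breeding
#' values.
#'
#' @param adjusted Per-animal adjusted phenotypes.
#' @param ebv Per-animal predicted breeding values (same order).
#' @return The slope, or `NA` with a warning when the breeding values have
#'   zero variance.
#' @export
bias_slope <- function(adjusted, ebv) {
  stopifnot(length(adjusted) == length(ebv))
  if (length(ebv) < 3L) stop("need at least 3 test animals for a slope")
  v <- stats::var(ebv)
  if (!is.finite(v) || v == 0) {
    warning("breeding values have zero variance; slope undefined")
    return(NA_real_)
  }
  stats::cov(adjusted, ebv) / v
}

#' Build the relationship structures an evaluation needs
#'
#' Computes, once, everything [run_cross_validation()] (or a plain fit)
#' needs: the pedigree `A^{-1}`, and — when genotypes are supplied — the
#' blended `G`, `A22`, `G^{-1}` and single-step `H^{-1}`.  Genotypes are
#' QC-filtered and mean-imputed here unless `qc = FALSE`.
#'
#' @param pedigree A `pedigree_table`.
#' @param genotypes Optional `genotype_set` of the genotyped animals.
#' @param cfg A [run_config()].
#' @param qc Apply [qc_filter()] before building G (default `TRUE`).
#' @return List with `ids`, `Ainv`, and when genotyped: `geno_ids`, `G`,
#'   `A22`, `Ginv`, `Hinv`, `qc_report`.
#' @export
build_relationships <- function(pedigree, genotypes = NULL,
                                cfg = run_config(), qc = TRUE) {
  Ainv <- build_a_inverse(pedigree)
  out <- list(ids = Ainv$ids, Ainv = Ainv)
  if (!is.null(genotypes)) {
    qr <- NULL
    if (qc) {
      res <- qc_filter(genotypes, cfg)
      genotypes <- res$genotypes
      qr <- res$report
    }
    genotypes <- impute_missing(genotypes)
    A <- build_a_matrix(pedigree)
    A22 <- extract_a22(A, genotypes$ids)
    G <- build_grm(genotypes, blend_weight = cfg$blend_weight, A22 = A22)
    out$geno_ids <- genotypes$ids
    out$G <- G
    out$A22 <- A22
    out$Ginv <- invert_relationship(G)
    out$Hinv <- build_h_inverse(Ainv, G, A22, genotypes$ids,
                                tau = cfg$tau, omega = cfg$omega)
    out$qc_report <- qr
  }
  out
}

# pick the inverse relationship structure for a method
method_kinv <- function(method, matrices) {
  switch(method,
         pblup = list(Kinv = matrices$Ainv, ids = matrices$ids),
         gblup = {
           if (is.null(matrices$Ginv)) stop("gblup needs genotypes")
           list(Kinv = matrices$Ginv, ids = matrices$geno_ids)
         },
         ssgblup = {
           if (is.null(matrices$Hinv)) stop("ssgblup needs genotypes")
           list(Kinv = matrices$Hinv, ids = matrices$ids)
         },
         stop("unknown method ", method))
}

#' Lactation-count cross-validation of a genetic evaluation
#'
#' For each of the three lactation-count folds: mask the fold's phenotypes,
#' fit the repeatability animal model on the remaining records, predict
#' breeding values for the test animals, adjust the held-out phenotypes
#' with the *training* fixed-effect estimates (no leakage), and compute the
#' test-set correlation, [accuracy()] and [bias_slope()].  The trait-level
#' report averages the three folds.
#'
#' @param records A `lactation_records` table.
#' @param method `"pblup"`, `"gblup"` or `"ssgblup"`.  For `"gblup"` every
#'   record animal must be genotyped.
#' @param cfg A [run_config()].
#' @param pedigree A `pedigree_table` (needed unless `matrices` given).
#' @param genotypes Optional `genotype_set` (needed for gblup / ssgblup
#'   unless `matrices` given).
#' @param matrices Optional precomputed [build_relationships()] output,
#'   shared across methods and traits.
#' @return Object of class `evaluation_report`: `folds` data frame (fold,
#'   n, n_test, correlation, accuracy, slope), `summary` (mean and sd over
#'   folds), `method`, `trait`.
#' @export
run_cross_validation <- function(records, method, cfg = run_config(),
                                 pedigree = NULL, genotypes = NULL,
                                 matrices = NULL) {
  stopifnot(inherits(records, "lactation_records"))
  method <- match.arg(method, c("pblup", "gblup", "ssgblup"))
  if (is.null(matrices)) {
    if (is.null(pedigree)) stop("pedigree (or matrices) required")
    matrices <- build_relationships(pedigree, genotypes, cfg)
  }
  mk <- method_kinv(method, matrices)
  if (method == "gblup") {
    ungeno <- setdiff(unique(records$animal_id), mk$ids)
    if (length(ungeno)) {
      stop("gblup requires all phenotyped animals genotyped; missing: ",
           paste(utils::head(ungeno, 5L), collapse = ", "))
    }
  }
  vc <- variance_components(cfg$h2, cfg$repeatability)
  folds <- assign_folds(records)
  rows <- lapply(folds, function(fold) {
    if (length(fold$test_ids) < 3L) {
      warning("fold ", fold$label, " has fewer than 3 test animals; ",
              "skipped")
      return(NULL)
    }
    train <- as_records(records[fold$train_rows, , drop = FALSE])
    design <- build_design(train, mk$ids)
    solution <- solve_mme(design, mk$Kinv, vc)
    test <- as_records(records[fold$test_rows, , drop = FALSE])
    adj <- adjust_phenotypes(test, solution)
    usable <- adj$animal_id
    if (length(usable) < 3L) {
      warning("fold ", fold$label, " has fewer than 3 usable test ",
              "animals; skipped")
      return(NULL)
    }
    ebv <- solution$ebv[usable]
    co <- stats::cor(ebv, adj$adj_pheno)
    data.frame(fold = fold$label, n = fold$n, n_test = length(usable),
               correlation = co,
               accuracy = accuracy(co, cfg$h2, cfg$repeatability, fold$n),
               slope = bias_slope(adj$adj_pheno, ebv))
  })
  folds_df <- do.call(rbind, rows)
  structure(list(method = method, trait = cfg$trait, folds = folds_df,
                 summary = list(
                   accuracy_mean = mean(folds_df$accuracy),
                   accuracy_sd = stats::sd(folds_df$accuracy),
                   slope_mean = mean(folds_df$slope),
                   slope_sd = stats::sd(folds_df$slope))),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Cross-validation report: trait %s, method %s\n", x$trait,
              x$method))
  print(x$folds, row.names = FALSE)
  cat(sprintf("accuracy %.3f +/- %.3f   slope %.3f +/- %.3f\n",
              x$summary$accuracy_mean, x$summary$accuracy_sd,
              x$summary$slope_mean, x$summary$slope_sd))
  invisible(x)
}

#' @rdname run_cross_validation
#' @param x An `evaluation_report`.
#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  data.frame(trait = x$trait, method = x$method,
             accuracy = x$summary$accuracy_mean,
             accuracy_sd = x$summary$accuracy_sd,
             slope = x$summary$slope_mean,
             slope_sd = x$summary$slope_sd)
}
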