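#' Allele frequency of a dosage column
#'
#' Frequency of the counted allele: `p = sum(dosages) / (2 * n)` over
#' non-missing entries.
#' @param dosage_column Numeric vector of 0/1/2/`NA` dosages.
#' @return `p` in \[0, 1\].
#' @export
allele_frequency <- function(dosage_column) {
  ok <- !is.na(dosage_column)
  if (!any(ok)) stop("all dosages missing; allele frequency undefined")
  sum(dosage_column[ok]) / (2 * sum(ok))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit of observed genotype counts
#' `(n_AA, n_Aa, n_aa)` against the expected proportions `(p^2, 2pq, q^2)`
#' computed from the observed allele frequency.  A monomorphic column
#' returns p-value 1 (nothing to test; such SNPs fall to the MAF filter).
#'
#' @param genotype_counts Integer vector of length 3: counts of the three
#'   genotype classes.
#' @return The chi-square p-value.
#' @export
hwe_test <- function(genotype_counts) {
  stopifnot(length(genotype_counts) == 3L, all(genotype_counts >= 0))
  n <- sum(genotype_counts)
  if (n == 0) stop("no genotype counts")
  p <- (2 * genotype_counts[[1L]] + genotype_counts[[2L]]) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0) return(1.0)
  expected <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((genotype_counts - expected)^2 / expected)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

# per-column genotype counts (n_2, n_1, n_0) and HWE p-values
hwe_pvalues <- function(dosages) {
  apply(dosages, 2L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(1.0)
    hwe_test(c(sum(col == 2), sum(col == 1), sum(col == 0)))
  })
}

#' SNP quality control
#'
#' Removes SNPs in a fixed order, each SNP counted once under its first
#' failing filter:
#' 1. `no_location` — missing chromosome or position;
#' 2. `non_autosomal` — chromosome outside the configured autosome set
#'    (default 1..29);
#' 3. `monomorphic` / `low_maf` — minor allele frequency 0, respectively
#'    below `maf_min` (default 0.05);
#' 4. `hwe` — Hardy-Weinberg chi-square p-value below `hwe_p_min`
#'    (default 1e-15).
#'
#' @param geno A [genotype_set()].
#' @param cfg A [run_config()] supplying `maf_min`, `hwe_p_min`, `autosomes`.
#' @return List with elements `genotypes` (filtered set) and `report`
#'   (class `qc_report`: per-filter counts, `n_in`, `n_out`).
#' @export
qc_filter <- function(geno, cfg = run_config()) {
  stopifnot(inherits(geno, "genotype_set"))
  m <- geno$dosages
  map <- geno$map
  n_in <- ncol(m)
  no_loc <- is.na(map$chromosome) | is.na(map$position)
  chr_num <- suppressWarnings(as.integer(map$chromosome))
  non_auto <- !no_loc & (is.na(chr_num) | !(chr_num %in% cfg$autosomes))
  p <- apply(m, 2L, function(col) {
    if (all(is.na(col))) NA_real_ else allele_frequency(col)
  })
  maf <- pmin(p, 1 - p)
  mono <- !no_loc & !non_auto & (is.na(maf) | maf == 0)
  low_maf <- !no_loc & !non_auto & !mono & maf < cfg$maf_min
  pass_so_far <- !(no_loc | non_auto | mono | low_maf)
  hwe_p <- rep(1.0, n_in)
  if (any(pass_so_far)) {
    hwe_p[pass_so_far] <- hwe_pvalues(m[, pass_so_far, drop = FALSE])
  }
  hwe_fail <- pass_so_far & hwe_p < cfg$hwe_p_min
  keep <- pass_so_far & !hwe_fail
  report <- structure(list(n_in = n_in,
                           no_location = sum(no_loc),
                           non_autosomal = sum(non_auto),
                           monomorphic = sum(mono),
                           low_maf = sum(low_maf),
                           hwe = sum(hwe_fail),
                           n_out = sum(keep)),
                      class = "qc_report")
  hb_log(paste0("qc: %d SNPs in; removed %d no-location, %d non-autosomal,",
                " %d monomorphic, %d MAF<%g, %d HWE p<%g; %d retained"),
         n_in, report$no_location, report$non_autosomal, report$monomorphic,
         report$low_maf, cfg$maf_min, report$hwe, cfg$hwe_p_min,
         report$n_out)
  filtered <- genotype_set(m[, keep, drop = FALSE],
                           map[keep, , drop = FALSE], ids = geno$ids)
  list(genotypes = filtered, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("SNP QC: %d in -> %d out (no_location %d,",
                     " non_autosomal %d, monomorphic %d, low_maf %d,",
                     " hwe %d)\n"),
              x$n_in, x$n_out, x$no_location, x$non_autosomal,
              x$monomorphic, x$low_maf, x$hwe))
  invisible(x)
}

#' @rdname qc_filter
#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(filter = c("no_location", "non_autosomal", "monomorphic",
                        "low_maf", "hwe"),
             removed = c(x$no_location, x$non_autosomal, x$monomorphic,
                         x$low_maf, x$hwe),
             n_in = x$n_in, n_out = x$n_out)
}

#' Mean-impute missing dosages
#'
#' Replaces each missing entry by `2p` of its SNP, i.e. the column mean of
#' the non-missing dosages — the neutral value for relationship-matrix
#' construction since the column is centred by `2p` afterwards.
#' @param geno A `genotype_set` (normally post-QC).
#' @return A complete `genotype_set`.
#' @export
impute_missing <- function(geno) {
  stopifnot(inherits(geno, "genotype_set"))
  m <- geno$dosages
  nmiss <- sum(is.na(m))
  if (nmiss > 0) {
    mu <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2L]]
    hb_log("impute: filled %d missing dosages with column means (2p)",
           nmiss)
  }
  out <- geno
  out$dosages <- m
  out
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' With observed allele frequencies `p_j` in the genotyped set, dosages are
#' centred as `Z = M - 2p` and the raw matrix is
#' `G_raw = Z Z' / (2 * sum p_j (1 - p_j))`.  To guarantee invertibility the
#' returned matrix is blended as `G = (1 - beta) G_raw + beta A22` with
#' `beta = blend_weight` (default 0.05); when no `A22` is supplied the
#' identity is used in its place.
#'
#' @param geno Imputed, QC-passed `genotype_set` (no missing entries,
#'   at least 2 SNPs).
#' @param blend_weight Blend weight `beta` in \[0, 1\].
#' @param A22 Optional `relationship_matrix` of kind `"A22"` with ids in
#'   exactly the genotype-set order.
#' @return `relationship_matrix` of kind `"G"`.
#' @export
build_grm <- function(geno, blend_weight = 0.05, A22 = NULL) {
  stopifnot(inherits(geno, "genotype_set"))
  m <- geno$dosages
  if (anyNA(m)) stop("genotypes contain missing values; run impute_missing()")
  if (ncol(m) < 1L) stop("need at least 1 SNP to build a GRM")
  p <- colMeans(m) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all SNPs monomorphic; GRM denominator is zero")
  Z <- sweep(m, 2L, 2 * p)
  G <- tcrossprod(Z) / denom
  if (blend_weight > 0) {
    if (!is.null(A22)) {
      stopifnot(inherits(A22, "relationship_matrix"),
                A22$kind %in% c("A22", "A"))
      if (!identical(A22$ids, geno$ids)) {
        stop("A22 id order does not match genotype set")
      }
      G <- (1 - blend_weight) * G + blend_weight * as.matrix(A22$matrix)
    } else {
      G <- (1 - blend_weight) * G + blend_weight * diag(nrow(G))
    }
  }
  G <- (G + t(G)) / 2
  relationship_matrix(G, geno$ids, kind = "G")
}

#' Dense inverse of a positive-definite relationship matrix
#' @param x `relationship_matrix` of kind `"G"` or `"A22"`.
#' @return `relationship_matrix` of the corresponding `_inverse` kind.
#' @export
invert_relationship <- function(x) {
  stopifnot(inherits(x, "relationship_matrix"))
  kind <- switch(x$kind, G = "G_inverse", A22 = "A22_inverse",
                 A = "A_inverse",
                 stop("cannot invert kind ", x$kind))
  ch <- tryCatch(chol(as.matrix(x$matrix)), error = function(e) {
    stop(x$kind, " is not positive definite; blend it toward A22 or the ",
         "identity (blend_weight > 0) before inverting", call. = FALSE)
  })
  inv <- chol2inv(ch)
  inv <- (inv + t(inv)) / 2
  relationship_matrix(inv, x$ids, kind = kind)
}
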