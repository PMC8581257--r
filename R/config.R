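#' Default heritabilities per trait
#'
#' Heritabilities for 305-day milk (MY), fat (FY) and protein (PY) yield used
#' as configuration defaults: 0.19, 0.17 and 0.19.  These are inputs to the
#' evaluation, not estimates produced by it.
#' @keywords internal
.default_h2 <- c(MY = 0.19, FY = 0.17, PY = 0.19)

#' Run configuration for a genetic evaluation
#'
#' Collects every tunable of an evaluation run: the trait, its variance
#' ratios, the relationship structure, SNP quality-control thresholds, the
#' genomic-relationship blending weight and solver settings.
#'
#' @param trait One of `"MY"`, `"FY"`, `"PY"` (305-day milk, fat, protein
#'   yield).
#' @param h2 Heritability in (0, 1).  Defaults to the per-trait values
#'   0.19 (MY), 0.17 (FY), 0.19 (PY).
#' @param repeatability Repeatability in (0, 1); must satisfy
#'   `h2 <= repeatability` (the additive variance cannot exceed the
#'   animal-plus-permanent-environment variance).  Default 0.40.
#' @param method Relationship structure: `"pblup"`, `"gblup"` or `"ssgblup"`.
#' @param maf_min Minimum minor allele frequency; SNPs below it are removed.
#'   Default 0.05.
#' @param hwe_p_min Hardy-Weinberg equilibrium chi-square p-value threshold;
#'   SNPs with p below it are removed.  Default 1e-15.
#' @param autosomes Integer vector of accepted autosome numbers, default 1:29.
#' @param blend_weight Weight `beta` of the pedigree submatrix (or identity)
#'   blended into the raw genomic relationship matrix, default 0.05.
#' @param tau,omega Scaling of the genomic and pedigree blocks of the
#'   single-step H-inverse, defaults 1.
#' @param solver_tol Convergence / consistency tolerance of the mixed-model
#'   solver, default 1e-10.
#' @param seed Integer random seed recorded with the run.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(trait = "MY", h2 = NULL, repeatability = 0.40,
                       method = c("pblup", "gblup", "ssgblup"),
                       maf_min = 0.05, hwe_p_min = 1e-15, autosomes = 1:29,
                       blend_weight = 0.05, tau = 1, omega = 1,
                       solver_tol = 1e-10, seed = 1L) {
  trait <- match.arg(trait, c("MY", "FY", "PY"))
  method <- match.arg(method)
  if (is.null(h2)) h2 <- unname(.default_h2[[trait]])
  stopifnot(is.numeric(h2), length(h2) == 1L,
            is.numeric(repeatability), length(repeatability) == 1L)
  if (!(h2 > 0 && h2 <= repeatability && repeatability < 1)) {
    stop("variance ratios must satisfy 0 < h2 <= repeatability < 1 ",
         sprintf("(got h2 = %g, repeatability = %g)", h2, repeatability))
  }
  if (!(maf_min >= 0 && maf_min < 0.5)) stop("maf_min must be in [0, 0.5)")
  if (!(blend_weight >= 0 && blend_weight <= 1)) {
    stop("blend_weight must be in [0, 1]")
  }
  structure(list(trait = trait, h2 = h2, repeatability = repeatability,
                 method = method, maf_min = maf_min, hwe_p_min = hwe_p_min,
                 autosomes = as.integer(autosomes),
                 blend_weight = blend_weight, tau = tau, omega = omega,
                 solver_tol = solver_tol, seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration (JSON)
#'
#' Configurations are stored as flat JSON so runs are reproducible from a
#' single text file.
#' @param path File path.
#' @return `read_config()` returns a [run_config()] object.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  do.call(run_config, raw[intersect(names(raw), known)])
}

#' @rdname read_config
#' @param cfg A [run_config()] object.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Variance components from heritability and repeatability
#'
#' Splits a phenotypic variance into additive (`sigma2_a`),
#' permanent-environment (`sigma2_pe`) and residual (`sigma2_e`) components
#' from `h2` and repeatability, and derives the mixed-model variance ratios
#' `lambda_a = sigma2_e / sigma2_a` and `lambda_pe = sigma2_e / sigma2_pe`.
#' When `repeatability == h2` the permanent-environment variance is zero and
#' that random effect is dropped from the model.
#'
#' @param h2 Heritability in (0, 1).
#' @param repeatability Repeatability, `h2 <= repeatability < 1`.
#' @param sigma2_p Phenotypic variance (default 1; the solver only uses the
#'   ratios).
#' @return List with `sigma2_a`, `sigma2_pe`, `sigma2_e`, `h2`,
#'   `repeatability`, `lambda_a`, `lambda_pe`.
#' @export
variance_components <- function(h2, repeatability, sigma2_p = 1) {
  if (!(h2 > 0 && h2 <= repeatability && repeatability < 1)) {
    stop("need 0 < h2 <= repeatability < 1")
  }
  sigma2_a <- h2 * sigma2_p
  sigma2_pe <- (repeatability - h2) * sigma2_p
  sigma2_e <- (1 - repeatability) * sigma2_p
  list(sigma2_a = sigma2_a, sigma2_pe = sigma2_pe, sigma2_e = sigma2_e,
       h2 = h2, repeatability = repeatability,
       lambda_a = sigma2_e / sigma2_a,
       lambda_pe = if (sigma2_pe > 0) sigma2_e / sigma2_pe else Inf)
}
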