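# Shared fixtures and independent oracles. Everything is built in code at
# test time; no data files.

options(herdblup.log_level = "NONE")

# --- hand-worked pedigrees -------------------------------------------------

# 1,2 founders; 3 and 4 full sibs from 1 x 2
ped_fullsib <- function() {
  as_pedigree(data.frame(animal = c("1", "2", "3", "4"),
                         sire = c("0", "0", "1", "1"),
                         dam = c("0", "0", "2", "2")))
}

# 1,2 founders; 3 = 1 x 2; 4 = 1 x 3 (sire-daughter mating, F4 = 0.25)
ped_sire_daughter <- function() {
  as_pedigree(data.frame(animal = c("1", "2", "3", "4"),
                         sire = c("0", "0", "1", "1"),
                         dam = c("0", "0", "2", "3")))
}

# random valid pedigree: founders first, later animals draw parents from
# earlier animals (possibly unknown)
random_pedigree <- function(n, n_founders = max(4L, n %/% 5L)) {
  animal <- as.character(seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1L):n) {
    pool <- seq_len(i - 1L)
    if (stats::runif(1) < 0.9) sire[i] <- as.character(sample(pool, 1L))
    if (stats::runif(1) < 0.9) dam[i] <- as.character(sample(pool, 1L))
  }
  as_pedigree(data.frame(animal = animal, sire = sire, dam = dam))
}

# --- 10-SNP QC fixture (hand tally: 2 no-location, 1 non-autosomal,
# 3 low-MAF, 1 HWE-violating, 3 clean -> 3 survive) -------------------------

qc_fixture <- function(n_animals = 80L) {
  stopifnot(n_animals %% 4 == 0)
  n <- n_animals
  hwe_exact <- c(rep(2, n / 4), rep(1, n / 2), rep(0, n / 4)) # chi2 = 0
  low <- c(rep(1, 3), rep(0, n - 3))                          # MAF 3/(2n)
  cols <- list(
    SNP01 = hwe_exact,           # no chromosome
    SNP02 = low,                 # no position AND low MAF: order check
    SNP03 = hwe_exact,           # chromosome 30
    SNP04 = low, SNP05 = low, SNP06 = low,   # MAF < 0.05
    SNP07 = rep(1, n),           # all het: chi2 = n, p << 1e-15
    SNP08 = hwe_exact, SNP09 = hwe_exact, SNP10 = hwe_exact)
  m <- do.call(cbind, cols)
  rownames(m) <- sprintf("C%03d", seq_len(n))
  map <- data.frame(snp_id = names(cols),
                    chromosome = c(NA, "5", "30", "7", "8", "9", "10",
                                   "11", "12", "13"),
                    position = c(500L, NA, seq(1000L, 8000L, 1000L)),
                    stringsAsFactors = FALSE)
  genotype_set(m, map)
}

# --- direct GLS/BLUP oracle ------------------------------------------------

# EBVs by the closed-form mixed-model identity: dense V inversion,
# u_hat = sigma2_a * K Za' V^-1 (y - X beta_gls). Independent of the MME
# solver path.
gls_oracle <- function(design, K, vc) {
  X <- as.matrix(design$X)
  Za <- as.matrix(design$Z_a)
  Zp <- as.matrix(design$Z_pe)
  y <- design$y
  V <- vc$sigma2_a * Za %*% K %*% t(Za) +
    diag(vc$sigma2_e, length(y))
  if (vc$sigma2_pe > 0) V <- V + vc$sigma2_pe * tcrossprod(Zp)
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  beta <- solve(XtVi %*% X, XtVi %*% y)
  res <- y - X %*% beta
  list(fixed = as.vector(beta),
       ebv = as.vector(vc$sigma2_a * K %*% t(Za) %*% Vi %*% res))
}

# --- random mixed-model instances -----------------------------------------

# small random data set with 1-3 records per phenotyped animal and a
# relationship structure of the requested kind ("A", "G" or "H")
random_instance <- function(n_animals = 30L, kind = c("A", "G", "H")) {
  kind <- match.arg(kind)
  ped <- random_pedigree(n_animals)
  ids <- ped$animal
  cows <- sample(ids, max(6L, round(0.6 * n_animals)))
  nr <- sample(1:3, length(cows), replace = TRUE)
  lact <- unlist(lapply(nr, function(k) sort(sample(1:3, k))))
  animal <- rep(cows, nr)
  records <- as_records(data.frame(
    animal_id = animal,
    breed = sample(c("B1", "B2"), length(animal), replace = TRUE),
    lactation_number = lact,
    hys = sample(c("h1", "h2", "h3"), length(animal), replace = TRUE),
    yield = 100 + stats::rnorm(length(animal)),
    trait = "MY"))
  vc <- variance_components(0.25, 0.45, sigma2_p = 1)
  if (kind == "A") {
    Kinv <- build_a_inverse(ped)
    K <- as_dense(build_a_matrix(ped))
    ids_k <- ids
  } else {
    n_g <- if (kind == "G") n_animals else max(5L, n_animals %/% 3L)
    gids <- if (kind == "G") ids else sort(sample(ids, n_g))
    m <- matrix(stats::rbinom(length(gids) * 60L, 2L, 0.5), length(gids),
                dimnames = list(gids, sprintf("s%02d", 1:60)))
    gs <- genotype_set(m, data.frame(snp_id = colnames(m),
                                     chromosome = "1",
                                     position = seq_len(60L)))
    A22 <- extract_a22(build_a_matrix(ped), gids)
    G <- build_grm(gs, blend_weight = 0.10, A22 = A22)
    if (kind == "G") {
      Kinv <- invert_relationship(G)
      K <- as_dense(G)
      ids_k <- gids
      records <- as_records(records[records$animal_id %in% gids, ,
                                    drop = FALSE])
    } else {
      Kinv <- build_h_inverse(build_a_inverse(ped), G, A22, gids)
      K <- solve(as.matrix(as_dense(Kinv)))
      K <- (K + t(K)) / 2
      ids_k <- ids
    }
  }
  if (length(unique(records$animal_id)) < 4L) return(NULL)
  design <- build_design(records, ids_k)
  list(records = records, design = design, Kinv = Kinv, K = K, vc = vc)
}

# tiny simulator settings used across tests (fast; a few hundred animals)
small_sim_cfg <- function(...) {
  args <- utils::modifyList(list(n_founder_females = 40,
                                 n_founder_males = 6, n_offspring = 70,
                                 n_snps = 400), list(...))
  do.call(sim_config, args)
}

# access the internal fixed-part predictor for cross-checking adjustment
fixed_fitted_for_test <- function(records, solution) {
  herdblup:::fixed_fitted(records, solution)
}
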