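#' Simulator configuration
#'
#' Defines the synthetic dairy-herd world: a six-generation pedigree of
#' roughly 2,640 animals in 12 herds linked by shared sires, three breeds
#' plus two cross classes, gene-dropped biallelic SNPs on 29 autosomes with
#' a configurable fraction of QC chaff, partial genotyping (about 46% of
#' the phenotyped cows), and 1-3 lactation records per cow whose mean and
#' spread match 305-day milk yield (1,573.2 kg, sd 505.9 kg) by default.
#'
#' @param n_founder_females,n_founder_males Founder counts (defaults 385
#'   and 15).
#' @param n_generations Discrete generations including founders, default 6.
#' @param n_offspring Offspring per post-founder generation, default 448
#'   (total about 2,640 animals).
#' @param n_sires Sires in service per generation, reused across herds,
#'   default 15.
#' @param prop_female Probability an offspring is female, default 0.90
#'   (dairy pedigrees record mostly cows plus a few sires).
#' @param record_prob Probability a non-founder female has lactation
#'   records, default 0.98.
#' @param n_herds Number of herds, default 12.
#' @param n_seasons Seasons per year in the herd-year-season level,
#'   default 2 (wet/dry calving bands keep contemporary groups at tens of
#'   records).
#' @param breeds Named additive mean offsets (kg) of the pure breeds,
#'   default BUL 0, BRA -5%, AME +5% of the trait mean.
#' @param cross_offsets Named offsets of the two cross classes.
#' @param breed_probs Founder-female breed probabilities.
#' @param n_autosomes Autosome count, default 29.
#' @param n_snps SNP count, desk default 5000 (the real chip retains
#'   60,827 post-QC).
#' @param frac_no_location,frac_non_autosomal,frac_low_maf,frac_hwe_fail
#'   Fractions of SNPs engineered to fail each QC rule so filter counts
#'   are exercised.
#' @param missing_rate Fraction of observed dosages masked to `NA`.
#' @param trait,mean_target,sd_target Trait tag and phenotypic mean / sd
#'   targets (kg).
#' @param h2,repeatability True variance ratios, defaults 0.19 and 0.40.
#' @param records_probs Distribution of records-per-cow over 1/2/3,
#'   default (0.364, 0.311, 0.325).
#' @param lactation_offsets Fixed lactation-number effects as fractions of
#'   the trait mean (parity 1 baseline; older cows yield more).
#' @param hys_sd_frac Herd-year-season effect sd as a fraction of the
#'   trait mean, default 0.15.
#' @param genotyped_fraction Fraction of phenotyped cows whose genotypes
#'   are revealed to the pipeline, default 904/1975.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_founder_females = 385, n_founder_males = 15,
                       n_generations = 6, n_offspring = 448, n_sires = 15,
                       prop_female = 0.90, record_prob = 0.98,
                       n_herds = 12, n_seasons = 2,
                       breeds = c(BUL = 0, BRA = -78.7, AME = 78.7),
                       cross_offsets = c(BULxBRA = -39.3, BULxAME = 39.3),
                       breed_probs = c(0.60, 0.25, 0.15),
                       n_autosomes = 29, n_snps = 5000,
                       frac_no_location = 0.02, frac_non_autosomal = 0.02,
                       frac_low_maf = 0.04, frac_hwe_fail = 0.02,
                       missing_rate = 0.01,
                       trait = "MY", mean_target = 1573.2,
                       sd_target = 505.9,
                       h2 = 0.19, repeatability = 0.40,
                       records_probs = c(0.364, 0.311, 0.325),
                       lactation_offsets = c(0, 0.04, 0.06),
                       hys_sd_frac = 0.15,
                       genotyped_fraction = 904 / 1975) {
  stopifnot(n_founder_females >= 2, n_founder_males >= 1,
            n_generations >= 1, prop_female > 0, prop_female <= 1,
            genotyped_fraction > 0, genotyped_fraction <= 1,
            sd_target > 0, abs(sum(records_probs) - 1) < 1e-8)
  structure(as.list(environment()), class = "sim_config")
}

# deterministic breed label of an offspring
offspring_breed <- function(sire_breed, dam_breed) {
  pure <- c("BUL", "BRA", "AME")
  out <- character(length(sire_breed))
  for (i in seq_along(sire_breed)) {
    s <- sire_breed[i]; d <- dam_breed[i]
    out[i] <- if (s == d) s
    else if (s %in% pure && d %in% pure) {
      if (setequal(c(s, d), c("BUL", "BRA"))) "BULxBRA"
      else if (setequal(c(s, d), c("BUL", "AME"))) "BULxAME"
      else "BULxBRA"   # rare BRA x AME matings bucketed into a cross class
    } else if (!s %in% pure) s else d
  }
  out
}

#' Simulate a herd pedigree
#'
#' Discrete generations; every offspring's parents sit in the previous
#' generation (acyclic by construction).  A small pool of sires per
#' generation is mated to dams across all herds, linking the herds the way
#' shared AI bulls do.  Breed labels are inherited, with mixed matings
#' falling into two cross classes.  Animal metadata (sex, generation, herd,
#' breed) is attached as attribute `"info"`.
#'
#' @param cfg A [sim_config()].
#' @return A `pedigree_table` with attribute `info`.
#' @export
simulate_pedigree <- function(cfg = sim_config()) {
  nf <- cfg$n_founder_females; nm <- cfg$n_founder_males
  id <- function(i) sprintf("A%05d", i)
  animal <- id(seq_len(nf + nm))
  sex <- c(rep("F", nf), rep("M", nm))
  generation <- rep(1L, nf + nm)
  herd <- sample(seq_len(cfg$n_herds), nf + nm, replace = TRUE)
  breed <- c(sample(names(cfg$breeds), nf, replace = TRUE,
                    prob = cfg$breed_probs),
             rep("BUL", nm))    # herd-linking sires are all BUL
  sire <- dam <- rep(NA_character_, nf + nm)
  nxt <- nf + nm + 1L
  if (cfg$n_generations > 1L) {
    for (g in 2:cfg$n_generations) {
      prev <- which(generation == g - 1L)
      dams_pool <- prev[sex[prev] == "F"]
      sires_all <- prev[sex[prev] == "M"]
      if (!length(sires_all) || !length(dams_pool)) break
      pool <- if (length(sires_all) > cfg$n_sires) {
        sample(sires_all, cfg$n_sires)
      } else sires_all
      n_off <- cfg$n_offspring
      s <- sample(rep(pool, 2L), n_off, replace = TRUE)
      d <- sample(rep(dams_pool, 2L), n_off, replace = TRUE)
      off <- id(seq.int(nxt, nxt + n_off - 1L))
      nxt <- nxt + n_off
      animal <- c(animal, off)
      sire <- c(sire, animal[s])
      dam <- c(dam, animal[d])
      sex <- c(sex, ifelse(stats::runif(n_off) < cfg$prop_female,
                           "F", "M"))
      generation <- c(generation, rep(g, n_off))
      herd <- c(herd, herd[d])
      breed <- c(breed, offspring_breed(breed[s], breed[d]))
    }
  }
  ped <- as_pedigree(data.frame(animal = animal, sire = sire, dam = dam,
                                stringsAsFactors = FALSE))
  info <- data.frame(animal = animal, sex = sex, generation = generation,
                     herd = herd, breed = breed, stringsAsFactors = FALSE)
  attr(ped, "info") <- info[match(ped$animal, info$animal), ]
  ped
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder alleles are drawn per SNP from Beta(2, 2)-distributed
#' frequencies (avoiding the extremes, so most SNPs survive the MAF
#' filter); every offspring receives one allele per parent per locus by
#' Mendelian sampling.  Configured fractions of SNPs are given missing map
#' locations, a non-autosomal chromosome, a low founder frequency, or an
#' engineered all-heterozygote column (a gross Hardy-Weinberg violation) so
#' the QC filters have known targets; these chaff SNPs carry no trait
#' effects.  Attributes: `true_dosages` (complete matrix before the missing
#' mask), `qc_class` (per-SNP factor), `founder_freq`.
#'
#' @param ped `pedigree_table` from [simulate_pedigree()].
#' @param cfg A [sim_config()].
#' @return A [genotype_set()] covering every pedigree animal.
#' @export
simulate_genotypes <- function(ped, cfg = sim_config()) {
  stopifnot(inherits(ped, "pedigree_table"))
  n <- nrow(ped); m <- cfg$n_snps
  pi <- parent_index(ped)
  classes <- rep("clean", m)
  ordx <- sample.int(m)
  take <- function(k) {
    if (k <= 0) return(integer(0))
    idx <- utils::head(ordx, k)
    ordx <<- ordx[-seq_len(k)]
    idx
  }
  cls_idx <- list(no_location = take(round(cfg$frac_no_location * m)),
                  non_autosomal = take(round(cfg$frac_non_autosomal * m)),
                  low_maf = take(round(cfg$frac_low_maf * m)),
                  hwe_fail = take(round(cfg$frac_hwe_fail * m)))
  for (nm in names(cls_idx)) classes[cls_idx[[nm]]] <- nm
  p <- stats::rbeta(m, 2, 2)
  p[cls_idx$low_maf] <- stats::runif(length(cls_idx$low_maf), 0.005, 0.03)
  pat <- matrix(0L, n, m)
  mat <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    s <- pi$s[i]; d <- pi$d[i]
    pat[i, ] <- if (s > 0L) {
      ifelse(stats::runif(m) < 0.5, pat[s, ], mat[s, ])
    } else as.integer(stats::runif(m) < p)
    mat[i, ] <- if (d > 0L) {
      ifelse(stats::runif(m) < 0.5, pat[d, ], mat[d, ])
    } else as.integer(stats::runif(m) < p)
  }
  dosage <- matrix(as.double(pat + mat), n, m)
  dosage[, cls_idx$hwe_fail] <- 1   # all-het columns: extreme HWE excess
  snp_id <- sprintf("SNP%05d", seq_len(m))
  chromosome <- as.character(sample(seq_len(cfg$n_autosomes), m,
                                    replace = TRUE))
  chromosome[cls_idx$non_autosomal] <- as.character(cfg$n_autosomes + 1L)
  chromosome[cls_idx$no_location] <- NA_character_
  position <- sample.int(1e8L, m, replace = TRUE)
  map <- data.frame(snp_id = snp_id, chromosome = chromosome,
                    position = position, stringsAsFactors = FALSE)
  observed <- dosage
  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(observed)) < cfg$missing_rate
    observed[mask] <- NA_real_
  }
  colnames(observed) <- snp_id
  rownames(observed) <- ped$animal
  gs <- genotype_set(observed, map)
  attr(gs, "true_dosages") <- `dimnames<-`(dosage,
                                           list(ped$animal, snp_id))
  attr(gs, "qc_class") <- classes
  attr(gs, "founder_freq") <- p
  gs
}

#' Simulate repeated lactation phenotypes with known truth
#'
#' True breeding values are built from the clean (non-chaff) SNPs with
#' effects drawn as `N(0, sigma2_a / (2 sum p(1-p)))`, then centred on the
#' population mean.  Phenotypes follow the repeatability animal model:
#' trait mean + breed + lactation-number + herd-year-season fixed effects
#' (each centred so the realized mean tracks the target), plus the true
#' breeding value, a permanent-environment effect per cow, and a residual
#' per record.  The three variance components are back-solved from the
#' target phenotypic sd after removing the analytic fixed-effect variance,
#' so the *random* part carries exactly `h2` and repeatability.  Residuals
#' of non-positive yields are redrawn (305-day yields are strictly
#' positive).
#'
#' @param ped `pedigree_table` with the simulator's `info` attribute.
#' @param geno [simulate_genotypes()] output.
#' @param cfg A [sim_config()].
#' @return List: `records` (a [as_records()] table) and `truth` (class
#'   `truth_set`: `tbv`, `pe`, `vc`, `snp_effects`, `fixed`).
#' @export
simulate_phenotypes <- function(ped, geno, cfg = sim_config()) {
  info <- attr(ped, "info")
  if (is.null(info)) stop("pedigree lacks simulator metadata (info)")
  true_d <- attr(geno, "true_dosages")
  if (is.null(true_d)) true_d <- impute_missing(geno)$dosages
  classes <- attr(geno, "qc_class")
  clean <- if (is.null(classes)) rep(TRUE, ncol(true_d)) else
    classes == "clean"
  Mc <- true_d[, clean, drop = FALSE]
  pj <- colMeans(Mc) / 2
  keep <- pj > 0 & pj < 1
  Mc <- Mc[, keep, drop = FALSE]
  pj <- pj[keep]
  denom <- 2 * sum(pj * (1 - pj))

  # which cows get records, and how many
  is_cow <- info$sex == "F" & info$generation > 1L
  has_rec <- is_cow & stats::runif(nrow(info)) < cfg$record_prob
  cows <- info$animal[has_rec]
  n_rec <- sample(1:3, length(cows), replace = TRUE,
                  prob = cfg$records_probs)
  lacts <- lapply(n_rec, function(k) sort(sample(1:3, k)))
  rec_animal <- rep(cows, n_rec)
  rec_lact <- unlist(lacts)
  ia <- match(rec_animal, info$animal)
  rec_breed <- info$breed[ia]
  # consecutive lactations fall in consecutive years; herdmates of one
  # generation calve in the same year band, so contemporary groups hold
  # tens of records (typical of a 12-herd institutional system)
  year <- 2000L + info$generation[ia] + rec_lact
  season <- sample(seq_len(cfg$n_seasons), length(rec_animal),
                   replace = TRUE)
  rec_hys <- sprintf("H%02d_%d_S%d", info$herd[ia], year, season)

  # fixed-effect values, each centred over the realized records
  breed_eff <- c(cfg$breeds, cfg$cross_offsets)
  b_val <- breed_eff[rec_breed]
  b_val <- b_val - mean(b_val)
  l_eff <- cfg$lactation_offsets * cfg$mean_target
  l_val <- l_eff[rec_lact]
  l_val <- l_val - mean(l_val)
  hys_levels <- unique(rec_hys)
  h_eff <- stats::rnorm(length(hys_levels),
                        sd = cfg$hys_sd_frac * cfg$mean_target)
  h_eff <- h_eff - mean(h_eff)
  names(h_eff) <- hys_levels
  h_val <- h_eff[rec_hys]
  fixed_val <- b_val + l_val + h_val

  var_fixed <- stats::var(fixed_val)
  sigma2_rand <- cfg$sd_target^2 - var_fixed
  if (sigma2_rand <= 0) {
    stop("fixed-effect variance exceeds the target phenotypic variance")
  }
  vc <- variance_components(cfg$h2, cfg$repeatability, sigma2_rand)

  u <- if (cfg$h2 > 0 && denom > 0) {
    stats::rnorm(ncol(Mc), sd = sqrt(vc$sigma2_a / denom))
  } else numeric(ncol(Mc))
  tbv <- as.vector(Mc %*% u)
  tbv <- tbv - mean(tbv)
  names(tbv) <- rownames(true_d)

  pe <- stats::setNames(stats::rnorm(length(cows),
                                     sd = sqrt(vc$sigma2_pe)), cows)
  e <- stats::rnorm(length(rec_animal), sd = sqrt(vc$sigma2_e))
  y <- cfg$mean_target + fixed_val + tbv[rec_animal] + pe[rec_animal] + e
  for (tries in 1:20) {        # 305-day yields are strictly positive
    bad <- y <= 0
    if (!any(bad)) break
    e[bad] <- stats::rnorm(sum(bad), sd = sqrt(vc$sigma2_e))
    y[bad] <- cfg$mean_target + fixed_val[bad] + tbv[rec_animal[bad]] +
      pe[rec_animal[bad]] + e[bad]
  }
  y[y <= 0] <- 1

  records <- as_records(data.frame(animal_id = rec_animal,
                                   breed = rec_breed,
                                   lactation_number = rec_lact,
                                   hys = rec_hys, yield = y,
                                   trait = cfg$trait,
                                   stringsAsFactors = FALSE))
  truth <- structure(list(tbv = tbv, pe = pe, vc = vc,
                          snp_effects = stats::setNames(u, colnames(Mc)),
                          fixed = list(breed = breed_eff,
                                       lactation = l_eff, hys = h_eff)),
                     class = "truth_set")
  list(records = records, truth = truth)
}

#' Simulate a complete herd data set
#'
#' Runs [simulate_pedigree()], [simulate_genotypes()] and
#' [simulate_phenotypes()] under one seed, then reveals genotypes for a
#' random `genotyped_fraction` of the phenotyped cows — the partial
#' genotyping the single-step method exists for.  The `GENO`-style subset
#' (phenotyped *and* genotyped animals, all usable by GBLUP) is accessible
#' with [geno_subset()].
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; same seed, same data.
#' @return Object of class `sim_data`: `pedigree`, `info`, `genotypes`
#'   (all animals), `genotypes_revealed`, `genotyped_ids`, `records`,
#'   `truth`, `cfg`.
#' @export
simulate_herd <- function(cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(ped, geno, cfg)
  pheno_ids <- unique(ph$records$animal_id)
  n_geno <- max(1L, round(cfg$genotyped_fraction * length(pheno_ids)))
  genotyped_ids <- sort(sample(pheno_ids, n_geno))
  structure(list(pedigree = ped, info = attr(ped, "info"),
                 genotypes = geno,
                 genotypes_revealed = subset_animals(geno, genotyped_ids),
                 genotyped_ids = genotyped_ids,
                 records = ph$records, truth = ph$truth, cfg = cfg),
            class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf(paste0("<sim_data: %d pedigree animals, %d records on %d ",
                     "cows, %d genotyped, %d SNPs>\n"),
              nrow(x$pedigree), nrow(x$records),
              length(unique(x$records$animal_id)),
              length(x$genotyped_ids), nrow(x$genotypes$map)))
  invisible(x)
}

#' GENO-style subset of a simulated data set
#'
#' Records restricted to the genotyped cows (every animal has both
#' phenotypes and genotypes), the data set shape GBLUP requires.
#' @param sim A `sim_data` object.
#' @return A `lactation_records` table.
#' @export
geno_subset <- function(sim) {
  stopifnot(inherits(sim, "sim_data"))
  as_records(sim$records[sim$records$animal_id %in% sim$genotyped_ids, ,
                         drop = FALSE])
}

#' Write a simulated data set to disk
#'
#' Writes `pedigree.csv`, `genotypes.raw` / `genotypes.map` (revealed
#' animals only), `phenotypes.csv`, `truth.csv` (animal, true breeding
#' value) and `sim_config.json` into a directory.
#' @param sim A `sim_data` object.
#' @param dir Output directory (created if absent).
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.csv"))
  write_genotypes(sim$genotypes_revealed, file.path(dir, "genotypes.raw"))
  write_phenotypes(sim$records, file.path(dir, "phenotypes.csv"))
  utils::write.csv(data.frame(animal_id = names(sim$truth$tbv),
                              tbv = unname(sim$truth$tbv)),
                   file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  cfg <- sim$cfg
  jsonlite::write_json(unclass(cfg), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
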