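#' Genotype set
#'
#' An animal-by-SNP dosage matrix (entries 0, 1, 2 or `NA`) aligned with a
#' per-SNP map (`snp_id`, `chromosome`, `position`).  Columns are reordered
#' to map order at construction; a SNP present in only one of matrix and map
#' is an error.  Chromosome is kept as character so sex chromosomes and
#' scaffold names survive until quality control classifies them.
#'
#' @param dosages Numeric matrix, rows = animals (rownames = ids), columns =
#'   SNPs (colnames = snp ids).
#' @param map Data frame with columns `snp_id`, `chromosome`, `position`.
#' @param ids Optional animal ids (defaults to rownames).
#' @return Object of class `genotype_set`: list with `dosages`, `map`, `ids`.
#' @export
genotype_set <- function(dosages, map, ids = rownames(dosages)) {
  stopifnot(is.matrix(dosages), is.data.frame(map))
  if (is.null(ids)) stop("animal ids required (rownames or ids=)")
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate animal ids in genotype set")
  need <- c("snp_id", "chromosome", "position")
  if (!all(need %in% names(map))) {
    stop("map must have columns snp_id, chromosome, position")
  }
  map$snp_id <- as.character(map$snp_id)
  map$chromosome <- normalize_id(map$chromosome)
  map$position <- suppressWarnings(as.integer(as.character(map$position)))
  if (anyDuplicated(map$snp_id)) stop("duplicate snp_id in map")
  snps <- colnames(dosages)
  if (is.null(snps)) {
    if (ncol(dosages) > 0L) {
      stop("dosage matrix must have SNP column names")
    }
    snps <- character(0)
  }
  extra <- setdiff(snps, map$snp_id)
  if (length(extra)) {
    stop("SNP(s) in dosage matrix but absent from map: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  absent <- setdiff(map$snp_id, snps)
  if (length(absent)) {
    stop("SNP(s) in map but absent from dosage matrix: ",
         paste(utils::head(absent, 5L), collapse = ", "))
  }
  dosages <- dosages[, map$snp_id, drop = FALSE]
  bad <- !(is.na(dosages) | dosages %in% c(0, 1, 2))
  if (any(bad)) {
    stop(sprintf("%d dosage value(s) outside {0,1,2,NA}", sum(bad)))
  }
  rownames(dosages) <- ids
  structure(list(dosages = dosages, map = map, ids = ids),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("<genotype_set: %d animals x %d SNPs, %.2f%% missing>\n",
              length(x$ids), nrow(x$map),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Read genotype dosages with their map
#'
#' Two dialects are supported, chosen by the dosage file extension:
#' * `.raw` — PLINK additive recode: whitespace-separated with header
#'   `FID IID PAT MAT SEX PHENOTYPE snp1_A ...`; the trailing allele suffix
#'   (`_A`, `_G`, ...) is stripped from SNP names; `NA` marks missing.
#'   The map is then PLINK `.map` (chromosome, snp id, cM, position, no
#'   header).
#' * anything else — CSV with an `id` first column and one column per SNP;
#'   map CSV with header `snp_id,chromosome,position`.
#'
#' @param path Dosage file.
#' @param map_path Map file.
#' @return A [genotype_set()].
#' @export
read_genotypes <- function(path, map_path) {
  if (grepl("\\.raw$", path)) {
    tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    snpcols <- setdiff(names(tab), meta)
    m <- as.matrix(tab[, snpcols, drop = FALSE])
    storage.mode(m) <- "double"
    colnames(m) <- sub("_[A-Za-z0-9]+$", "", snpcols)
    rownames(m) <- as.character(tab$IID)
    mp <- utils::read.table(map_path, header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("chromosome", "snp_id", "cm",
                                          "position"))
    map <- mp[, c("snp_id", "chromosome", "position")]
  } else {
    tab <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(tab[[1L]])
    map <- utils::read.csv(map_path, stringsAsFactors = FALSE)
  }
  genotype_set(m, map)
}

#' @rdname read_genotypes
#' @param geno A `genotype_set`.
#' @param path Output `.raw` (or `.csv`) path; the map is written next to it
#'   with the matching extension.
#' @export
write_genotypes <- function(geno, path, map_path = NULL) {
  stopifnot(inherits(geno, "genotype_set"))
  if (grepl("\\.raw$", path)) {
    if (is.null(map_path)) map_path <- sub("\\.raw$", ".map", path)
    tab <- data.frame(FID = geno$ids, IID = geno$ids, PAT = 0, MAT = 0,
                      SEX = 0, PHENOTYPE = -9, check.names = FALSE)
    m <- geno$dosages
    colnames(m) <- paste0(colnames(m), "_A")
    utils::write.table(cbind(tab, m), path, row.names = FALSE,
                       quote = FALSE, sep = " ")
    mp <- geno$map
    mp$chromosome[is.na(mp$chromosome)] <- "0"
    mp$position[is.na(mp$position)] <- 0L
    utils::write.table(mp[, c("chromosome", "snp_id")] |>
                         cbind(cm = 0, position = mp$position),
                       map_path, row.names = FALSE, col.names = FALSE,
                       quote = FALSE, sep = "\t")
  } else {
    if (is.null(map_path)) map_path <- sub("\\.csv$", ".map.csv", path)
    utils::write.csv(data.frame(id = geno$ids, geno$dosages,
                                check.names = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    utils::write.csv(geno$map, map_path, row.names = FALSE, quote = FALSE)
  }
  invisible(c(path, map_path))
}

#' Subset a genotype set by animal
#' @param geno A `genotype_set`.
#' @param ids Animal ids to keep, in the requested order.
#' @export
subset_animals <- function(geno, ids) {
  stopifnot(inherits(geno, "genotype_set"))
  ids <- as.character(ids)
  missing <- setdiff(ids, geno$ids)
  if (length(missing)) {
    stop("animals absent from genotype set: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  genotype_set(geno$dosages[ids, , drop = FALSE], geno$map, ids = ids)
}
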