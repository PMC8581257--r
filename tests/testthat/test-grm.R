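test_that("allele frequency counts alleles", {
  expect_equal(allele_frequency(c(0, 1, 2, 2)), 0.625)   # MAF 0.375
  expect_equal(allele_frequency(c(0, 0, 0)), 0)
  expect_equal(allele_frequency(c(1, 1, 1, 1)), 0.5)
  expect_equal(allele_frequency(c(0, 2, NA)), 0.5)       # missing skipped
  expect_error(allele_frequency(c(NA, NA)), "missing")
})

test_that("HWE chi-square test matches hand arithmetic", {
  expect_equal(hwe_test(c(25, 50, 25)), 1.0)             # exact HWE
  # (30,40,30): expected (25,50,25), chi2 = 4, p ~ 0.0455
  expect_equal(hwe_test(c(30, 40, 30)),
               pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(hwe_test(c(30, 40, 30)), 0.0455, tolerance = 1e-3)
  # (50,0,50): chi2 = 100 on 1 df, far below the removal threshold
  expect_lt(hwe_test(c(50, 0, 50)), 1e-15)
  expect_equal(hwe_test(c(10, 0, 0)), 1.0)               # monomorphic
})

test_that("QC removes SNPs in fixed order with first-failure counting", {
  res <- qc_filter(qc_fixture(), run_config())
  r <- res$report
  expect_equal(r$no_location, 2)
  expect_equal(r$non_autosomal, 1)
  expect_equal(r$monomorphic, 0)
  expect_equal(r$low_maf, 3)
  expect_equal(r$hwe, 1)
  expect_equal(r$n_out, 3)
  expect_identical(res$genotypes$map$snp_id, c("SNP08", "SNP09", "SNP10"))
  # SNP02 has low MAF *and* no position: counted once, under no_location
  expect_equal(r$n_in - with(r, no_location + non_autosomal + monomorphic +
                                low_maf + hwe), r$n_out)

  # idempotent: filtering the filtered set removes nothing
  res2 <- qc_filter(res$genotypes, run_config())
  expect_equal(res2$report$n_out, res2$report$n_in)
  expect_equal(res2$genotypes$dosages, res$genotypes$dosages)

  # boundary: MAF 0.04 fails, the threshold is strict 'less than 0.05'
  m <- cbind(s1 = c(rep(1, 8), rep(0, 92)))
  rownames(m) <- sprintf("a%d", 1:100)
  gs <- genotype_set(m, data.frame(snp_id = "s1", chromosome = "1",
                                   position = 1L))
  expect_equal(qc_filter(gs, run_config())$report$low_maf, 1)
})

test_that("mean imputation fills missing dosages with 2p", {
  m <- cbind(s1 = c(0, 2, NA), s2 = c(2, 2, NA), s3 = c(0, 1, 2))
  rownames(m) <- c("a", "b", "c")
  gs <- genotype_set(m, data.frame(snp_id = colnames(m), chromosome = "1",
                                   position = 1:3))
  imp <- impute_missing(gs)
  expect_equal(unname(imp$dosages[3, "s1"]), 1.0)  # 2p = 2 * 0.5
  expect_equal(unname(imp$dosages[3, "s2"]), 2.0)  # 2p = 2 * 1
  expect_identical(imp$dosages[, "s3"], gs$dosages[, "s3"])
})

test_that("GRM matches the hand-computed single-SNP case and identities", {
  # 2 animals, 1 SNP, dosages (0,2): p = 0.5, Z = (-1,+1), denom = 0.5
  m <- cbind(s1 = c(0, 2))
  rownames(m) <- c("a", "b")
  gs <- genotype_set(m, data.frame(snp_id = "s1", chromosome = "1",
                                   position = 1L))
  G <- as_dense(build_grm(gs, blend_weight = 0))
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2))

  # column centering forces the grand sum of G_raw to zero
  set.seed(5)
  m2 <- matrix(rbinom(40 * 25, 2, 0.4), 40, 25,
               dimnames = list(sprintf("a%02d", 1:40),
                               sprintf("s%02d", 1:25)))
  gs2 <- genotype_set(m2, data.frame(snp_id = colnames(m2),
                                     chromosome = "1",
                                     position = 1:25))
  G2 <- as_dense(build_grm(gs2, blend_weight = 0))
  expect_lt(abs(sum(G2)), 1e-8)

  # blend limits: beta = 1 returns A22 exactly; blended G is PD
  A22 <- relationship_matrix(diag(40) * 1.05, rownames(m2), kind = "A22")
  expect_equal(as_dense(build_grm(gs2, blend_weight = 1, A22 = A22)),
               as_dense(A22))
  expect_no_error(chol(as_dense(build_grm(gs2, blend_weight = 0.05,
                                          A22 = A22))))
  # id-order mismatch with A22 is an error
  A22r <- relationship_matrix(diag(40), rev(rownames(m2)), kind = "A22")
  expect_error(build_grm(gs2, blend_weight = 0.05, A22 = A22r), "order")
  # all-monomorphic input has a zero denominator
  m3 <- cbind(s1 = c(0, 0), s2 = c(2, 2))
  rownames(m3) <- c("a", "b")
  gs3 <- genotype_set(m3, data.frame(snp_id = c("s1", "s2"),
                                     chromosome = "1", position = 1:2))
  expect_error(build_grm(gs3, blend_weight = 0), "monomorphic")
})

test_that("G_raw diagonal averages 1 on unrelated HWE genotypes", {
  set.seed(9)
  n <- 60; m <- 3000
  p <- rbeta(m, 2, 2)
  dos <- vapply(p, function(pp) rbinom(n, 2, pp), numeric(n))
  dimnames(dos) <- list(sprintf("a%02d", 1:n), sprintf("s%04d", 1:m))
  gs <- genotype_set(dos, data.frame(snp_id = colnames(dos),
                                     chromosome = "1",
                                     position = seq_len(m)))
  G <- as_dense(build_grm(gs, blend_weight = 0))
  expect_equal(mean(diag(G)), 1.0, tolerance = 0.05)
  expect_lt(mean(abs(G[upper.tri(G)])), 0.1)
})
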