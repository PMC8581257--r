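test_that("design matrices use reference coding and correct incidence", {
  rec <- as_records(data.frame(
    animal_id = c("a", "a", "b"),
    breed = "BUL", lactation_number = c(1, 2, 3), hys = "h1",
    yield = c(1000, 1100, 900), trait = "MY"))
  d <- build_design(rec, c("a", "b", "c"))
  # one breed, one hys: intercept + 2 lactation contrasts only
  expect_identical(ncol(d$X), 3L)
  expect_true("(Intercept)" %in% colnames(d$X))
  # Z_a covers all animals incl. unphenotyped 'c'; Z_pe only phenotyped
  expect_identical(dim(d$Z_a), c(3L, 3L))
  expect_identical(dim(d$Z_pe), c(3L, 2L))
  expect_equal(Matrix::colSums(d$Z_pe)[[1]], 2)  # animal a has 2 records
  expect_error(build_design(rec, c("a", "c")), "missing")
})

test_that("balanced two-factor design is full column rank", {
  grid <- expand.grid(breed = c("B1", "B2"), hys = c("h1", "h2"),
                      lactation_number = 1:2)
  rec <- as_records(data.frame(
    animal_id = sprintf("a%d", seq_len(nrow(grid))),
    breed = grid$breed, lactation_number = grid$lactation_number,
    hys = grid$hys, yield = 1000, trait = "MY"))
  d <- build_design(rec, unique(rec$animal_id))
  expect_identical(qr(d$X)$rank, ncol(d$X))
})

test_that("degenerate MME solutions are exact", {
  # all yields identical: mu = the value, EBVs and PE all zero
  rec <- as_records(data.frame(
    animal_id = c("1", "2", "3", "3"),
    breed = "B", lactation_number = c(1, 1, 1, 2), hys = "h",
    yield = 1500, trait = "MY"))
  ped <- as_pedigree(data.frame(animal = c("1", "2", "3"), sire = "0",
                                dam = "0"))
  d <- build_design(rec, ped$animal)
  vc <- variance_components(0.19, 0.40)
  sol <- solve_mme(d, build_a_inverse(ped), vc)
  expect_equal(unname(sol$fixed["(Intercept)"]), 1500, tolerance = 1e-8)
  expect_lt(max(abs(sol$ebv)), 1e-8)
  expect_lt(max(abs(sol$pe)), 1e-8)
})

test_that("independent single records shrink to h2 * (y - ybar)", {
  # unrelated animals, one record each, mean-only fixed part:
  # BLUP reduces to the selection index EBV_i = h2 (y_i - ybar)
  set.seed(3)
  n <- 12
  y <- 1000 + rnorm(n, sd = 50)
  rec <- as_records(data.frame(
    animal_id = sprintf("a%02d", 1:n), breed = "B", lactation_number = 1,
    hys = "h", yield = y, trait = "MY"))
  ped <- as_pedigree(data.frame(animal = sprintf("a%02d", 1:n),
                                sire = "0", dam = "0"))
  d <- build_design(rec, ped$animal)
  h2 <- 0.19
  sol <- solve_mme(d, build_a_inverse(ped),
                   variance_components(h2, 0.40))
  expect_equal(unname(sol$ebv), h2 * (y - mean(y)), tolerance = 1e-8)
})

test_that("MME equals the direct GLS/BLUP oracle for all K kinds", {
  set.seed(101)
  for (kind in c("A", "G", "H")) {
    inst <- NULL
    while (is.null(inst)) {
      inst <- suppressWarnings(random_instance(25, kind))
    }
    sol <- solve_mme(inst$design, inst$Kinv, inst$vc)
    oracle <- gls_oracle(inst$design, inst$K, inst$vc)
    expect_lt(max(abs(unname(sol$ebv) - oracle$ebv)), 1e-8)
    expect_lt(max(abs(unname(sol$fixed) - oracle$fixed)), 1e-8)
  }
})

test_that("solutions are invariant to record order and to the K label", {
  set.seed(17)
  inst <- NULL
  while (is.null(inst)) inst <- suppressWarnings(random_instance(20, "A"))
  sol <- solve_mme(inst$design, inst$Kinv, inst$vc)
  perm <- sample(nrow(inst$records))
  d2 <- build_design(as_records(inst$records[perm, ]), inst$design$ids)
  sol2 <- solve_mme(d2, inst$Kinv, inst$vc)
  expect_equal(sol$ebv, sol2$ebv, tolerance = 1e-8)
  expect_equal(sol$fixed[names(sol2$fixed)], sol2$fixed,
               tolerance = 1e-8)
  # one solver, three methods: relabelling the same Kinv changes nothing
  relab <- relationship_matrix(inst$Kinv$matrix, inst$Kinv$ids,
                               kind = "H_inverse")
  sol3 <- solve_mme(inst$design, relab, inst$vc)
  expect_identical(sol$ebv, sol3$ebv)
})

test_that("adjusted phenotypes subtract fixed effects and average", {
  rec <- as_records(data.frame(
    animal_id = c("a", "a", "b"),
    breed = "B", lactation_number = c(1, 2, 1), hys = c("h1", "h1", "h2"),
    yield = c(1600, 1640, 1500), trait = "MY"))
  ped <- as_pedigree(data.frame(animal = c("a", "b"), sire = "0",
                                dam = "0"))
  d <- build_design(rec, ped$animal)
  sol <- solve_mme(d, build_a_inverse(ped), variance_components(0.19, 0.4))
  adj <- adjust_phenotypes(rec, sol)
  fitted <- fixed_fitted_for_test(rec, sol)
  manual <- tapply(rec$yield - fitted, rec$animal_id, mean)
  expect_equal(adj$adj_pheno, as.numeric(manual[adj$animal_id]),
               tolerance = 1e-10)
  expect_identical(adj$n_records[adj$animal_id == "a"], 2L)

  # records with unseen fixed levels are excluded, with a count
  rec2 <- as_records(data.frame(
    animal_id = c("a", "b"), breed = "B", lactation_number = c(1, 1),
    hys = c("hNEW", "h1"), yield = c(1550, 1450), trait = "MY"))
  adj2 <- adjust_phenotypes(rec2, sol)
  expect_identical(attr(adj2, "n_dropped"), 1L)
  expect_identical(adj2$animal_id, "b")
})
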