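test_that("pedigree reading normalises, adds founders and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam", "1,0,0", "2,,NA", "3,1,2"), tmp)
  ped <- read_pedigree(tmp)
  expect_s3_class(ped, "pedigree_table")
  expect_setequal(ped$animal, c("1", "2", "3"))
  expect_true(is.na(ped$sire[ped$animal == "2"]))

  # implicit founders: a single row naming unseen parents yields 3 animals
  writeLines(c("animal,sire,dam", "3,1,2"), tmp)
  ped2 <- read_pedigree(tmp)
  expect_setequal(ped2$animal, union("3", c("1", "2")))
  expect_identical(nrow(ped2), 3L)

  # round trip is identity (up to row order, which is topological)
  out <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, out)
  again <- read_pedigree(out)
  expect_identical(again[order(again$animal), ],
                   ped[order(ped$animal), ], ignore_attr = TRUE)
})

test_that("pedigree validation rejects cycles and duplicates", {
  expect_error(as_pedigree(data.frame(animal = "1", sire = "1",
                                      dam = "0")),
               "cycle")
  expect_error(as_pedigree(data.frame(animal = c("1", "2", "2"),
                                      sire = 0, dam = 0)),
               "duplicate")
  # two-animal ancestry loop
  expect_error(as_pedigree(data.frame(animal = c("1", "2"),
                                      sire = c("2", "1"),
                                      dam = c("0", "0"))),
               "cycle")
})

test_that("phenotype reading filters, validates and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal_id,breed,lactation_number,hys,my_305",
               "c1,BUL,1,h1_2001_s1,1573.2",
               "c2,BRA,2,h1_2001_s1,",
               "c3,AME,1,h2_2001_s2,1200.5"), tmp)
  rec <- read_phenotypes(tmp, "MY")
  expect_identical(nrow(rec), 2L)            # missing yield dropped
  expect_equal(rec$yield[rec$animal_id == "c1"], 1573.2)

  # herd/year/season triplet concatenates into an opaque hys level
  writeLines(c("animal_id,breed,lactation_number,herd,year,season,my_305",
               "c1,BUL,1,7,2001,2,1500"), tmp)
  rec2 <- read_phenotypes(tmp, "MY")
  expect_identical(rec2$hys, "7_2001_2")

  # invalid lactation numbers and duplicates are hard errors
  writeLines(c("animal_id,breed,lactation_number,hys,my_305",
               "c1,BUL,4,h1,1500"), tmp)
  expect_error(read_phenotypes(tmp, "MY"), "lactation_number")
  writeLines(c("animal_id,breed,lactation_number,hys,my_305",
               "c1,BUL,3,h1,1500", "c1,BUL,3,h2,1600"), tmp)
  expect_error(read_phenotypes(tmp, "MY"), "duplicate lactation")

  # empty input: empty table, no error
  writeLines("animal_id,breed,lactation_number,hys,my_305", tmp)
  expect_identical(nrow(read_phenotypes(tmp, "MY")), 0L)

  # round trip
  out <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(rec, out)
  expect_equal(read_phenotypes(out, "MY"), rec, ignore_attr = TRUE)
})

test_that("genotype reading validates against the map and round-trips", {
  m <- matrix(c(0, 0, 0, 0, 0, 0), 2, 3,
              dimnames = list(c("a1", "a2"), c("s1", "s2", "s3")))
  map <- data.frame(snp_id = c("s1", "s2", "s3"), chromosome = "1",
                    position = 1:3)
  gs <- genotype_set(m, map)
  expect_true(all(gs$dosages == 0))

  expect_error(genotype_set(m, map[1:2, ]), "absent from map")
  bad <- m; bad[1, 1] <- 3
  expect_error(genotype_set(bad, map), "outside")

  # PLINK .raw / .map round trip, including missing values
  gs$dosages[2, 3] <- NA
  raw <- withr::local_tempfile(fileext = ".raw")
  write_genotypes(gs, raw)
  back <- read_genotypes(raw, sub("\\.raw$", ".map", raw))
  expect_identical(back$ids, gs$ids)
  expect_equal(back$dosages, gs$dosages)
  expect_identical(back$map$snp_id, gs$map$snp_id)

  # CSV dialect round trip
  csv <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(gs, csv)
  back2 <- read_genotypes(csv, sub("\\.csv$", ".map.csv", csv))
  expect_equal(back2$dosages, gs$dosages)
})

test_that("run_config enforces the variance-ratio ordering and defaults", {
  cfg <- run_config()
  expect_equal(cfg$h2, 0.19)        # MY default
  expect_equal(run_config(trait = "FY")$h2, 0.17)
  expect_equal(cfg$maf_min, 0.05)
  expect_equal(cfg$hwe_p_min, 1e-15)
  expect_identical(cfg$autosomes, 1:29)
  expect_error(run_config(h2 = 0.5, repeatability = 0.4), "h2")
  expect_error(run_config(h2 = 0, repeatability = 0.4), "h2")

  tmp <- withr::local_tempfile(fileext = ".json")
  write_config(run_config(trait = "FY", method = "gblup"), tmp)
  cfg2 <- read_config(tmp)
  expect_equal(cfg2$trait, "FY")
  expect_equal(cfg2$method, "gblup")
  expect_equal(cfg2$h2, 0.17)
})

test_that("relationship matrix CSV export/import round-trips", {
  A <- build_a_matrix(ped_sire_daughter())
  tmp <- withr::local_tempfile(fileext = ".csv")
  export_matrix(A, tmp)
  back <- import_matrix(tmp, kind = "A")
  expect_identical(back$ids, A$ids)
  expect_equal(as_dense(back), as_dense(A), tolerance = 1e-12)
})
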