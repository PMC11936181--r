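test_that("pose files parse to per-configuration energies in file order", {
  f <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(c("MODEL 1", "REMARK VINA RESULT:    -7.0    0.000    0.000",
               "ENDMDL"), f)
  expect_identical(parsePoseFile(f), -7.0)

  writeLines(unlist(lapply(c(-7.2, -6.9, -6.5), function(e) c(
    "MODEL", sprintf("REMARK VINA RESULT: %.1f 0.000 0.000", e),
    "ATOM      1  C   LIG A   1       0.000   0.000   0.000",
    "ENDMDL"))), f)
  expect_identical(parsePoseFile(f), c(-7.2, -6.9, -6.5))
})

test_that("pose parsing errors name the file and offending line", {
  f <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(c("MODEL 1", "ENDMDL"), f)
  expect_error(parsePoseFile(f), basename(f), fixed = TRUE)
  writeLines(c("MODEL 1", "REMARK VINA RESULT: oops 0 0", "ENDMDL"), f)
  expect_error(parsePoseFile(f), "line 2")
})

test_that("pose-file round trip through the generator is lossless", {
  lib <- generateLibrary(librarySpec(n_compounds = 3, seed = 7))
  d <- withr::local_tempdir()
  generatePoseFiles(lib$runs, d)
  back <- readPoseDir(d)
  for (cid in unique(lib$runs$compound_id)) {
    for (tid in defaultTargets()) {
      orig <- lib$runs$energy_kcal_mol[lib$runs$compound_id == cid &
                                         lib$runs$target_id == tid]
      got <- back$energy_kcal_mol[back$compound_id == cid &
                                    back$target_id == tid]
      expect_identical(got, orig)
    }
  }
})

test_that("energy tables parse with and without configuration_index", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,target_id,configuration_index,energy_kcal_mol",
               "c1,ERK2,1,-7.0"), f)
  runs <- parseEnergyTable(f)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$energy_kcal_mol, -7.0)

  writeLines(c("compound_id\ttarget_id\tenergy_kcal_mol",
               "c1\tERK2\t-7.0", "c1\tERK2\t-6.5",
               "c2\tJNK2\t-8.0", "c2\tJNK2\t-7.5"), f)
  runs <- parseEnergyTable(f)
  expect_equal(nrow(runs), 4L)
  expect_equal(runs$configuration_index, c(1L, 2L, 1L, 2L))
})

test_that("shuffled energy-table rows parse to the sorted table", {
  rows <- c("c2,JNK2,2,-7.5", "c1,ERK2,1,-7.0", "c2,JNK2,1,-8.0",
            "c1,ERK2,2,-6.5")
  hdr <- "compound_id,target_id,configuration_index,energy_kcal_mol"
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(hdr, rows), f1)
  writeLines(c(hdr, sort(rows)), f2)
  expect_identical(parseEnergyTable(f1), parseEnergyTable(f2))
})

test_that("energy-table contract errors: duplicates and bad numbers", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,target_id,configuration_index,energy_kcal_mol",
               "c1,ERK2,1,-7.0", "c1,ERK2,1,-6.0"), f)
  expect_error(parseEnergyTable(f), "duplicate")
  writeLines(c("compound_id,target_id,configuration_index,energy_kcal_mol",
               "c1,ERK2,1,-7.0", "c1,ERK2,2,xyz"), f)
  expect_error(parseEnergyTable(f), "row 2")
})

test_that("representative energy reduces by minimum or mean", {
  e <- c(-7.2, -6.9, -6.5)
  expect_identical(representativeEnergy(e), -7.2)
  expect_equal(representativeEnergy(e, "mean"), -6.8666666667, tolerance = 1e-9)
  expect_identical(representativeEnergy(-5.0), -5.0)
  expect_identical(representativeEnergy(-5.0, "mean"), -5.0)
  expect_error(representativeEnergy(numeric()), "empty")
})

test_that("minimum reduction never exceeds mean reduction", {
  set.seed(11)
  for (i in 1:50) {
    e <- rnorm(sample(1:20, 1), -6, 1)
    expect_lte(representativeEnergy(e, "minimum"),
               representativeEnergy(e, "mean"))
  }
})

test_that("energy matrix assembly matches cell-wise reduction and row order", {
  runs <- rbind(pairRuns("a", "ERK2", c(-7.2, -6.9)),
                pairRuns("a", "JNK2", c(-6.0, -6.4)),
                pairRuns("b", "ERK2", c(-8.0, -7.0)),
                pairRuns("b", "JNK2", c(-5.0, -5.5)))
  for (mode in c("minimum", "mean")) {
    em <- buildEnergyMatrix(runs, c("a", "b"), c("ERK2", "JNK2"), mode = mode)
    for (cid in c("a", "b")) for (tid in c("ERK2", "JNK2")) {
      e <- runs$energy_kcal_mol[runs$compound_id == cid &
                                  runs$target_id == tid]
      expect_equal(energies(em)[cid, tid], representativeEnergy(e, mode))
    }
  }
  # permutation invariance in input run order
  perm <- sample(nrow(runs))
  em1 <- buildEnergyMatrix(runs, c("a", "b"), c("ERK2", "JNK2"))
  em2 <- buildEnergyMatrix(runs[perm, ], c("a", "b"), c("ERK2", "JNK2"))
  expect_identical(energies(em1), energies(em2))
})

test_that("matrix assembly enforces density and drops strays with a warning", {
  runs <- rbind(pairRuns("a", "ERK2", -7), pairRuns("a", "JNK2", -6))
  expect_error(buildEnergyMatrix(runs, c("a", "b"), c("ERK2", "JNK2")),
               "b/ERK2.*b/JNK2")
  expect_warning(
    em <- buildEnergyMatrix(runs, "a", "ERK2"),
    "a/JNK2")
  expect_identical(dim(energies(em)), c(1L, 1L))
})

test_that("energy matrix TSV round-trips at 4-decimal precision", {
  em <- makeEnergyMatrix(round(rnorm(10, -7), 4), c("a", "b"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEnergyMatrix(em, f)
  expect_equal(energies(readEnergyMatrix(f)), energies(em), tolerance = 1e-12)
})

test_that("model quality flips strictly above 90% most-favoured residues", {
  expect_identical(classifyModelQuality(c(90.3, 92.2, 90.8, 79.0, 80.9)),
                   c("good", "good", "good", "not_good", "not_good"))
  expect_identical(classifyModelQuality(90.0), "not_good")
  expect_error(classifyModelQuality(101), "\\[0, 100\\]")
  expect_error(classifyModelQuality(-1), "\\[0, 100\\]")
  # monotone: never drops from good back to not_good as pct rises
  x <- seq(0, 100, by = 0.5)
  g <- classifyModelQuality(x) == "good"
  expect_true(all(diff(as.integer(g)) >= 0))
  expect_identical(proteinQuality()$quality,
                   c("good", "good", "good", "not_good", "not_good"))
})

test_that("EnergyMatrix validity rejects non-finite or unnamed input", {
  m <- matrix(c(-7, NA), 1, 2,
              dimnames = list("a", c("ERK2", "JNK2")))
  expect_error(EnergyMatrix(m), "finite")
  expect_error(EnergyMatrix(matrix(-7, 1, 1)), "rownames")
})
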