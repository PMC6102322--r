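test_that("a hand-written PED/MAP fixture is transcribed exactly", {
  dir <- withr::local_tempdir()
  writeLines(c("1\tm1\t0\t100", "1\tm2\t0\t200", "1\tm3\t0\t300"),
             file.path(dir, "fix.map"))
  # s1: A A | A C | C C   s2: C C | 0 0 | A A
  writeLines(c("B1 s1 0 0 0 -9 A A A C C C",
               "B2 s2 0 0 0 -9 C C 0 0 A A"),
             file.path(dir, "fix.ped"))
  gd <- read_plink(file.path(dir, "fix"))
  expect_equal(unname(gd$calls), rbind(c(0L, 1L, 2L), c(2L, NA, 0L)))
  expect_equal(gd$samples$breed, c("B1", "B2"))
  expect_equal(gd$map$marker_id, c("m1", "m2", "m3"))
  expect_equal(gd$map$allele_a, rep("A", 3))
  expect_equal(gd$map$allele_b, rep("C", 3))
})

test_that("markers are re-sorted by chromosome and position on read", {
  dir <- withr::local_tempdir()
  writeLines(c("2\tmA\t0\t500", "1\tmB\t0\t900", "1\tmC\t0\t100"),
             file.path(dir, "s.map"))
  writeLines(c("B1 s1 0 0 0 -9 A C A A C C",
               "B1 s2 0 0 0 -9 C C A C A A"), file.path(dir, "s.ped"))
  gd <- read_plink(file.path(dir, "s"))
  expect_equal(gd$map$marker_id, c("mC", "mB", "mA"))
  expect_equal(unname(gd$calls), rbind(c(2L, 0L, 1L), c(0L, 1L, 2L)))
})

test_that("round trip is the identity for both dialects on simulated data", {
  sim <- small_sim(seed = 42)
  gd <- sim$dataset
  # PED carries no allele codes for unobserved alleles: restrict to markers
  # where both alleles are seen, the only case the text dialect can encode
  nb <- colSums(gd$calls, na.rm = TRUE)
  nn <- 2 * colSums(!is.na(gd$calls))
  both <- (nb > 0 & nb < nn) | colSums(gd$calls == 1L, na.rm = TRUE) > 0
  poly <- genotype_dataset(gd$calls[, both], gd$map[both, ], gd$samples)

  dir <- withr::local_tempdir()
  write_plink(poly, file.path(dir, "rt"), "ped")
  back <- read_plink(file.path(dir, "rt"))
  expect_equal(unname(back$calls), unname(poly$calls))
  expect_equal(back$map, poly$map)
  expect_equal(back$samples, poly$samples)

  # binary dialect round-trips everything, monomorphic markers included
  write_plink(gd, file.path(dir, "rtb"), "bed")
  backb <- read_plink(file.path(dir, "rtb"))
  expect_equal(unname(backb$calls), unname(gd$calls))
  expect_equal(backb$map, gd$map)
  expect_equal(backb$samples, gd$samples)
})

test_that("breed table overrides the family-ID breed labels", {
  sim <- small_sim(seed = 7)
  dir <- withr::local_tempdir()
  write_plink(sim$dataset, file.path(dir, "b"), "bed")
  ids <- sim$dataset$samples$sample_id
  gd <- read_plink(file.path(dir, "b"),
                   breed_table = data.frame(sample_id = ids[1:3],
                                            breed = "OVERRIDE"))
  expect_equal(gd$samples$breed[1:3], rep("OVERRIDE", 3))
  expect_equal(gd$samples$breed[-(1:3)], sim$dataset$samples$breed[-(1:3)])
})

test_that("degenerate and malformed inputs error or pass through cleanly", {
  dir <- withr::local_tempdir()
  # empty-marker dataset writes valid zero-variant files
  gd0 <- genotype_dataset(matrix(integer(), 2, 0),
                          data.frame(marker_id = character(),
                                     chromosome = character(),
                                     position_bp = integer(),
                                     allele_a = character(),
                                     allele_b = character()),
                          data.frame(sample_id = c("a", "b"), breed = "X"))
  write_plink(gd0, file.path(dir, "empty"), "ped")
  back <- read_plink(file.path(dir, "empty"))
  expect_equal(dim(back$calls), c(2L, 0L))

  expect_error(read_plink(file.path(dir, "nothing")), "no .bed or .ped")
  writeLines("1\tm1\t0\t100", file.path(dir, "bad.map"))
  writeLines("B1 s1 0 0 0 -9 A Z", file.path(dir, "bad.ped"))
  expect_error(read_plink(file.path(dir, "bad")), "allele code")

  writeLines(c("1\tm1\t0\t100", "1\tm1\t0\t200"), file.path(dir, "dup.map"))
  writeLines("B1 s1 0 0 0 -9 A A C C", file.path(dir, "dup.ped"))
  expect_error(read_plink(file.path(dir, "dup")), "duplicate marker_id")
})

test_that("co-located markers keep input order with a warning", {
  map <- data.frame(marker_id = c("x", "y"), chromosome = "1",
                    position_bp = c(100L, 100L),
                    allele_a = "A", allele_b = "C")
  smp <- data.frame(sample_id = "s", breed = "B")
  expect_warning(gd <- genotype_dataset(matrix(c(0L, 2L), 1), map, smp),
                 "share a position")
  expect_equal(gd$map$marker_id, c("x", "y"))
})
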