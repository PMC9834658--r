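test_that("PED tokens map to minor-allele dosages with '0' as missing", {
  ped <- c(
    "f1 s1 0 0 0 -9 A A A G 0 0",
    "f2 s2 0 0 0 -9 A A A A A A"
  )
  map <- c("1\tm1\t0\t100", "1\tm2\t0\t200", "2\tm3\t0\t300")
  ped_path <- withr::local_tempfile(fileext = ".ped")
  map_path <- withr::local_tempfile(fileext = ".map")
  writeLines(ped, ped_path)
  writeLines(map, map_path)

  g <- read_ped_map(ped_path, map_path)
  expect_equal(g$samples, c("s1", "s2"))
  expect_equal(g$markers$chromosome, c("1", "1", "2"))
  # m1 monomorphic A: dosage 0; m2 A is major (3 of 4), G minor; m3: s1 missing
  expect_equal(unname(g$calls[1, ]), c(0L, 1L, NA))
  expect_equal(unname(g$calls[2, ]), c(0L, 0L, 0L))
  expect_equal(g$markers$allele_b[2], "G")
})

test_that("a marker with three observed alleles is rejected", {
  ped_path <- withr::local_tempfile(fileext = ".ped")
  map_path <- withr::local_tempfile(fileext = ".map")
  writeLines(c("f1 s1 0 0 0 -9 A G", "f2 s2 0 0 0 -9 A T"), ped_path)
  writeLines("1\tm1\t0\t100", map_path)
  expect_error(read_ped_map(ped_path, map_path), "3 observed alleles")
})

test_that("dimension mismatch and duplicate sample ids are rejected", {
  ped_path <- withr::local_tempfile(fileext = ".ped")
  map_path <- withr::local_tempfile(fileext = ".map")
  writeLines("f1 s1 0 0 0 -9 A A G G", ped_path)
  writeLines("1\tm1\t0\t100", map_path)  # 1 marker, PED carries 2
  expect_error(read_ped_map(ped_path, map_path), "expected")

  writeLines(c("f1 s1 0 0 0 -9 A A", "f2 s1 0 0 0 -9 A G"), ped_path)
  expect_error(read_ped_map(ped_path, map_path), "duplicate sample ids")
})

test_that("write/read round-trip is the identity on oriented matrices", {
  g <- orient_minor(random_geno(5, 10, missing_rate = 0.1, seed = 101))
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  write_ped_map(g, ped, map)
  g2 <- read_ped_map(ped, map)
  expect_identical(g2$calls, g$calls)
  expect_equal(g2$markers$name, g$markers$name)
  expect_equal(g2$markers$position_bp, g$markers$position_bp)
})

test_that("write-read-write produces byte-identical files on a 100 x 500 panel", {
  g <- orient_minor(random_geno(100, 500, missing_rate = 0.02, seed = 202))
  p1 <- withr::local_tempfile(fileext = ".ped")
  m1 <- withr::local_tempfile(fileext = ".map")
  p2 <- withr::local_tempfile(fileext = ".ped")
  m2 <- withr::local_tempfile(fileext = ".map")
  write_ped_map(g, p1, m1)
  write_ped_map(read_ped_map(p1, m1), p2, m2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(readLines(m1), readLines(m2))
})

test_that("heterozygous genotypes are written allele_a then allele_b", {
  g <- make_geno(matrix(1L, 1, 1), samples = "s1")
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  write_ped_map(g, ped, map)
  expect_match(readLines(ped), "A G$")
})

test_that("an empty marker panel writes 6-column PED rows and a 0-row MAP", {
  g <- geno(matrix(integer(0), 2, 0),
            tibble::tibble(name = character(), chromosome = character(),
                           position_bp = integer(), allele_a = character(),
                           allele_b = character()),
            samples = c("s1", "s2"))
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  write_ped_map(g, ped, map)
  expect_equal(length(readLines(map)), 0)
  expect_equal(lengths(strsplit(readLines(ped), " ")), c(6L, 6L))
})

test_that("allele frequencies satisfy p + q = 1 and match direct counting", {
  g <- random_geno(30, 50, missing_rate = 0.15, seed = 303)
  af <- allele_freq(g)
  called <- af$T > 0
  expect_true(all(abs(af$p[called] + af$q[called] - 1) < 1e-12))
  j <- 17
  x <- g$calls[, j]
  expect_equal(af$q[j], sum(x, na.rm = TRUE) / (2 * sum(!is.na(x))))
  expect_equal(af$T[j], 2L * sum(!is.na(x)))
})

test_that("metadata/phenotype tables load, validate and report unmatched ids", {
  sp <- withr::local_tempfile(fileext = ".tsv")
  pp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    id = c("a", "b", "c"), breed = "x", birth_date = "2015-01-01",
    birth_place = "farm1"
  ), sp)
  readr::write_tsv(tibble::tibble(
    id = c("a", "b", "c", "d"), body_mass_g = c(1, 2, 3, 4) * 1e4,
    age_days = c(40, 50, 60, 70)
  ), pp)

  res <- suppressMessages(read_tables(sp, pp, genotype_ids = c("a", "b", "c")))
  expect_equal(nrow(res$samples), 3)
  expect_equal(nrow(res$phenotypes), 4)
  expect_equal(res$unmatched$id, "d")
  expect_equal(res$unmatched$table, "phenotypes")
})

test_that("non-numeric phenotype fields fail naming the offending row", {
  pp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tbody_mass_g\tage_days", "a\t18000\t60", "b\t20000\tabc"), pp)
  expect_error(read_tables(pheno_path = pp), "age_days at row 2")
})

test_that("missing mandatory columns are reported by name", {
  sp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(id = "a", breed = "x"), sp)
  expect_error(read_tables(sp), "birth_date")
})
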