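test_that("bundled panel loads with unsampled mothers and putative sires flagged", {
  p <- sgigas_panel()
  expect_s3_class(p, "msat_panel")
  expect_equal(nrow(p$masses), 16L)
  expect_equal(nrow(p$adults), 16L)
  expect_setequal(panel_loci(p), c("MS-03", "MS-26", "MS-31", "MS-34"))
  # masses 23 and 36: mother never sampled
  unsampled <- p$masses$mass_id[is.na(p$masses$maternal_id)]
  expect_setequal(unsampled, c("23", "36"))
  # exactly four masses have a genotyped putative sire
  with_sire <- p$masses$mass_id[!is.na(p$masses$putative_sire_id)]
  expect_setequal(with_sire, c("20", "27", "30", "33"))
  # ND cells became NULL allele sets
  expect_null(mass_alleles(p, "29", "MS-26"))
  expect_null(mass_alleles(p, "32", "MS-31"))
  expect_equal(mass_alleles(p, "26", "MS-31"), c(53L, 57L, 59L, 61L, 63L))
})

test_that("empty mass table yields a panel with zero masses", {
  d <- sgigas_fixture_dir()
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("mass_id,maternal_id,maternal_status,putative_sire_id,MS-03,MS-26,MS-31,MS-34",
             tmp)
  p <- read_panel(file.path(d, "adults.csv"), tmp, file.path(d, "loci.csv"))
  expect_equal(nrow(p$masses), 0L)
})

test_that("read-write-read round trip preserves the panel", {
  p <- sgigas_panel()
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "a.csv"); fm <- file.path(dir, "m.csv")
  fl <- file.path(dir, "l.csv")
  write_panel(p, fa, fm, fl)
  p2 <- read_panel(fa, fm, fl)
  expect_equal(p2$loci, p$loci)
  expect_equal(p2$adults, p$adults)
  expect_equal(p2$masses, p$masses)
})

test_that("malformed tables fail with informative errors", {
  d <- sgigas_fixture_dir()
  dir <- withr::local_tempdir()
  # duplicate adult id
  a <- read.csv(file.path(d, "adults.csv"), check.names = FALSE)
  a2 <- rbind(a, a[1, ])
  fa <- file.path(dir, "adults.csv")
  write.csv(a2, fa, row.names = FALSE)
  expect_error(read_panel(fa, file.path(d, "masses.csv"),
                          file.path(d, "loci.csv")),
               "duplicate adult_id")
  # non-integer allele names row and column
  a3 <- a; a3[2, "MS-03_a"] <- "x13"
  write.csv(a3, fa, row.names = FALSE)
  expect_error(read_panel(fa, file.path(d, "masses.csv"),
                          file.path(d, "loci.csv")),
               "row 2.*MS-03_a")
  # bad allele set cell in the mass table
  m <- read.csv(file.path(d, "masses.csv"), check.names = FALSE,
                colClasses = "character")
  m[1, "MS-26"] <- "283;n/a"
  fm <- file.path(dir, "masses.csv")
  write.csv(m, fm, row.names = FALSE)
  expect_error(read_panel(file.path(d, "adults.csv"), fm,
                          file.path(d, "loci.csv")),
               "mass 20, locus MS-26")
  # unresolvable maternal id (not the NS sentinel)
  m2 <- read.csv(file.path(d, "masses.csv"), check.names = FALSE,
                 colClasses = "character")
  m2[1, "maternal_id"] <- "GHOST"
  write.csv(m2, fm, row.names = FALSE)
  expect_error(read_panel(file.path(d, "adults.csv"), fm,
                          file.path(d, "loci.csv")),
               "maternal_id does not resolve")
})

test_that("genotype allele order is normalized to allele_a <= allele_b", {
  loci <- data.frame(locus = "LA", repeat_motif = "AC")
  adults <- data.frame(adult_id = "A1", social_status = "unknown",
                       shell_length_mm = NA_real_,
                       LA_a = 104L, LA_b = 100L)
  masses <- data.frame(mass_id = character(), maternal_id = character(),
                       maternal_status = character(),
                       putative_sire_id = character())
  masses$alleles <- list()
  p <- msat_panel(loci, adults, masses)
  expect_equal(adult_genotype(p, "A1", "LA"), c(100L, 104L))
})

test_that("every bundled egg mass carries a maternal allele at each genotyped locus", {
  expect_equal(nrow(validate_maternal_consistency(sgigas_panel())), 0L)
})

test_that("maternal consistency flags disjoint allele sets and skips no-data loci", {
  p <- toy_panel(mass_sets = list(LA = c(104), LB = NULL))
  # mother A001 is (100,102) at LA: mass allele 104 shares nothing
  v <- validate_maternal_consistency(p)
  expect_equal(nrow(v), 1L)
  expect_equal(v$locus, "LA")  # LB skipped: no data
})

test_that("adult-panel allele filter removes unseen alleles, logs them, and warns on emptied sets", {
  p <- toy_panel(mass_sets = list(LA = c(100, 999), LB = c(555)))
  expect_warning(f <- filter_alleles_to_adult_panel(p), "all alleles removed")
  expect_equal(mass_alleles(f, "m1", "LA"), 100)
  expect_null(mass_alleles(f, "m1", "LB"))
  removed <- attr(f, "removed")
  expect_setequal(removed$allele, c(999, 555))
})

test_that("allele filter is idempotent and monotone in the adult set", {
  p <- toy_panel(mass_sets = list(LA = c(100, 110), LB = c(200)))
  f1 <- filter_alleles_to_adult_panel(p)
  f2 <- filter_alleles_to_adult_panel(f1)
  expect_equal(f2$masses$alleles, f1$masses$alleles)
  expect_equal(nrow(attr(f2, "removed")), 0L)
  # add an adult carrying the previously absent allele 110
  p2 <- p
  p2$adults <- rbind(p2$adults,
                     data.frame(adult_id = "A003", social_status = "solitary",
                                shell_length_mm = NA_real_,
                                LA_a = 110L, LA_b = 110L,
                                LB_a = 200L, LB_b = 200L))
  f3 <- filter_alleles_to_adult_panel(p2)
  expect_true(all(mass_alleles(f1, "m1", "LA") %in%
                    mass_alleles(f3, "m1", "LA")))
  expect_true(110 %in% mass_alleles(f3, "m1", "LA"))
})
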