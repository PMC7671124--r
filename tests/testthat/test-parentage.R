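test_that("non-maternal allele counting handles known, unknown, and missing data", {
  # egg mass 26, MS-31: pool {53,57,59,61,63} vs mother (57,57) -> 4
  expect_equal(nonmaternal_alleles(c(53, 57, 59, 61, 63), c(57, 57)), 4L)
  expect_equal(nonmaternal_alleles(c(115, 117), c(115, 117)), 0L)
  # unknown mother: two most-explaining alleles assumed maternal
  expect_equal(nonmaternal_alleles(c(115, 117, 121), NULL), 1L)
  expect_equal(nonmaternal_alleles(c(115, 117), NULL), 0L)
  expect_true(is.na(nonmaternal_alleles(NULL, c(1, 2))))
})

test_that("per-mass sire estimates follow the heterozygous/homozygous sire rules", {
  p <- sgigas_panel()
  m26 <- p$masses[p$masses$mass_id == "26", ]
  mom26 <- lapply(panel_loci(p), function(l) adult_genotype(p, "M26", l))
  names(mom26) <- panel_loci(p)
  est <- estimate_sires(m26, mom26)
  expect_equal(est$min_sires_conservative, 2L)  # ceil(4/2) at MS-31
  expect_equal(est$sires_liberal, 4L)
  m27 <- p$masses[p$masses$mass_id == "27", ]
  mom27 <- lapply(panel_loci(p), function(l) adult_genotype(p, "M27", l))
  names(mom27) <- panel_loci(p)
  est27 <- estimate_sires(m27, mom27)
  expect_equal(est27$min_sires_conservative, 1L)
  expect_equal(est27$sires_liberal, 1L)
  # all-maternal pool still implies one sire (floor)
  est0 <- estimate_sires(list(LA = c(1, 2)), list(LA = c(1, 2)))
  expect_equal(est0$min_sires_conservative, 1L)
  expect_equal(est0$sires_liberal, 1L)
  # no informative locus at all
  expect_error(estimate_sires(list(LA = NULL), list(LA = c(1, 2))),
               "uninformative mass")
})

test_that("the bundled dataset reproduces the reported min-sires column for all 16 masses", {
  p <- sgigas_panel()
  est <- estimate_sires_panel(p)
  pub <- read.csv(file.path(sgigas_fixture_dir(), "published_calls.csv"),
                  colClasses = c(mass_id = "character"))
  expect_equal(est$min_sires_conservative[match(pub$mass_id, est$mass_id)],
               pub$min_sires)
  # unknown-mother masses use the subtract-two rule and are flagged
  expect_false(est$maternal_known[est$mass_id == "23"])
  expect_false(est$maternal_known[est$mass_id == "36"])
})

test_that("multiple-paternity frequency is 3/16 conservative and 8/16 liberal", {
  p <- sgigas_panel()
  cons <- count_multiple_paternity(p, "conservative")
  expect_equal(cons$n_multiple, 3L)
  expect_equal(cons$n_total, 16L)
  expect_equal(cons$frequency, 0.1875)
  lib <- count_multiple_paternity(p, "liberal")
  expect_equal(lib$n_multiple, 8L)
  expect_equal(lib$frequency, 0.5)
  est <- estimate_sires_panel(p)
  expect_equal(range(est$sires_liberal), c(1L, 4L))
  expect_equal(range(est$min_sires_conservative), c(1L, 2L))
})

test_that("pair classification calls EP on novel alleles and MO otherwise", {
  p <- sgigas_panel()
  geno <- function(id) {
    g <- lapply(panel_loci(p), function(l) adult_genotype(p, id, l))
    names(g) <- panel_loci(p)
    g
  }
  m20 <- classify_pair(p$masses[p$masses$mass_id == "20", ],
                       geno("M20"), geno("PP20"))
  expect_equal(m20$call, "EP")
  expect_true(all(c("MS-31", "MS-34") %in% m20$evidence_loci))
  expect_equal(m20$evidence_alleles[["MS-31"]], c(59, 61))
  expect_equal(m20$evidence_alleles[["MS-34"]], 244)
  m27 <- classify_pair(p$masses[p$masses$mass_id == "27", ],
                       geno("M27"), geno("M30"))
  expect_equal(m27$call, "MO")
  expect_length(m27$evidence_loci, 0)
  # allele sets within mother+sire union at every locus -> MO
  mo <- classify_pair(list(LA = c(1, 3)), list(LA = c(1, 2)),
                      list(LA = c(3, 4)))
  expect_equal(mo$call, "MO")
  # unsampled putative sire -> UNDETERMINED
  und <- classify_pair(list(LA = c(1, 9)), list(LA = c(1, 2)), NULL)
  expect_equal(und$call, "UNDETERMINED")
})

test_that("putative sire exclusion diagnostics match the narrative pattern", {
  p <- sgigas_panel()
  ps <- pair_summary(p)
  absent <- setNames(ps$calls$sire_absent_loci, ps$calls$mass_id)
  # two of the three extra-pair masses lack any partner allele at >= 1 locus
  expect_true(nzchar(absent[["20"]]))
  expect_true(nzchar(absent[["33"]]))
  # the third is compatible with partner plus one extra-pair sire
  expect_false(nzchar(absent[["30"]]))
})

test_that("pair summary reproduces 3 EP and 1 MO over the four genotyped pairs", {
  p <- sgigas_panel()
  ps <- pair_summary(p)
  expect_equal(c(ps$n_EP, ps$n_MO, ps$n_undetermined), c(3L, 1L, 0L))
  calls <- setNames(ps$calls$call, ps$calls$mass_id)
  expect_equal(calls[c("20", "27", "30", "33")],
               c("20" = "EP", "27" = "MO", "30" = "EP", "33" = "EP"))
  # panel without putative sires: everything skipped
  p2 <- p
  p2$masses$putative_sire_id <- NA_character_
  ps2 <- pair_summary(p2)
  expect_equal(c(ps2$n_EP, ps2$n_MO, ps2$n_undetermined), c(0L, 0L, 0L))
})

test_that("sire estimates obey ordering and monotonicity invariants", {
  set.seed(90)
  for (rep in 1:50) {
    k <- sample(1:6, 1)
    pool <- sort(sample(100:120, k))
    mom <- sample(100:120, 2, replace = TRUE)
    est <- estimate_sires(list(L = pool), list(L = mom))
    expect_gte(est$min_sires_conservative, 1L)
    expect_lte(est$min_sires_conservative, est$sires_liberal)
    expect_lte(est$sires_liberal, 2L * est$min_sires_conservative)
    # adding an allele never decreases either estimate
    extra <- sample(setdiff(121:130, pool), 1)
    est2 <- estimate_sires(list(L = sort(c(pool, extra))), list(L = mom))
    expect_gte(est2$min_sires_conservative, est$min_sires_conservative)
    expect_gte(est2$sires_liberal, est$sires_liberal)
  }
})
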