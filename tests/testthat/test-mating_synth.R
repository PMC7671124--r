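test_that("population generation is reproducible and respects the configuration", {
  cfg <- synth_config(seed = 42)
  pop1 <- generate_population(cfg)
  pop2 <- generate_population(cfg)
  expect_identical(pop1$panel$adults, pop2$panel$adults)
  expect_identical(pop1$truth$freqs, pop2$truth$freqs)
  # allele counts within the configured 4-7 range, frequencies sum to 1
  for (f in pop1$truth$freqs) {
    expect_true(length(f) %in% 4:7)
    expect_equal(sum(f), 1)
  }
  # everyone paired when prop_paired = 1, with symmetric partners
  cfg1 <- synth_config(seed = 8, n_adults = 40, prop_paired = 1)
  pop <- generate_population(cfg1)
  prt <- pop$truth$partner
  expect_false(anyNA(prt))
  expect_identical(unname(prt[prt]), names(prt))
  # status-specific shell lengths around their configured means
  cfg2 <- synth_config(seed = 9, n_adults = 4000)
  ad <- generate_population(cfg2)$panel$adults
  m <- tapply(ad$shell_length_mm, ad$social_status, mean)
  expect_equal(unname(m[["paired"]]), 50.6, tolerance = 0.02)
  expect_equal(unname(m[["solitary"]]), 47.2, tolerance = 0.02)
})

test_that("a strictly monogamous generator produces only within-pair single-sire masses", {
  cfg <- synth_config(seed = 7, prop_paired = 1, p_within_pair_use = 1,
                      p_extra_pair = 0, sires_per_mass_dist = c("1" = 1))
  pop <- generate_population(cfg)
  gm <- generate_masses(pop, cfg,
                        mothers = pop$panel$adults$adult_id[1:50])
  expect_true(all(gm$truth$n_sires == 1L))
  expect_true(all(gm$truth$sires ==
                    pop$truth$partner[gm$truth$maternal_id]))
  ps <- pair_summary(gm$panel)
  expect_equal(ps$n_EP, 0L)
  expect_equal(ps$n_MO, nrow(gm$panel$masses))
  expect_equal(count_multiple_paternity(gm$panel)$n_multiple, 0L)
})

test_that("pooled allele sets contain every transmitted allele at detection threshold 1", {
  cfg <- synth_config(seed = 13, n_adults = 30, prop_paired = 0,
                      sires_per_mass_dist = c("2" = 1),
                      n_embryos_pooled = 200)
  pop <- generate_population(cfg)
  set.seed(99)
  gm <- generate_masses(pop, cfg, mothers = pop$panel$adults$adult_id[1:10])
  for (i in seq_len(10)) {
    tr <- gm$truth[i, ]
    sires <- strsplit(tr$sires, ";")[[1]]
    counts <- as.integer(strsplit(tr$embryo_counts, ";")[[1]])
    expect_equal(sum(counts), 200L)
    for (loc in panel_loci(gm$panel)) {
      pool <- mass_alleles(gm$panel, tr$mass_id, loc)
      parents <- unique(c(adult_genotype(gm$panel, tr$maternal_id, loc),
                          unlist(lapply(sires[counts > 0],
                                        adult_genotype, panel = gm$panel,
                                        locus = loc))))
      expect_true(all(pool %in% parents))
      # mother transmits to every embryo, so a maternal allele always shows
      expect_true(any(pool %in% adult_genotype(gm$panel, tr$maternal_id,
                                               loc)))
    }
  }
  # a high detection threshold can only shrink the pooled sets
  cfg2 <- cfg; cfg2$detection_min_count <- 150L
  set.seed(99)  # same mating and inheritance draws, higher threshold
  gm2 <- generate_masses(pop, cfg2, mothers = pop$panel$adults$adult_id[1:10])
  for (i in seq_len(10))
    for (loc in panel_loci(gm2$panel)) {
      s1 <- mass_alleles(gm$panel, gm$truth$mass_id[i], loc)
      s2 <- mass_alleles(gm2$panel, gm2$truth$mass_id[i], loc)
      expect_true(is.null(s2) || all(s2 %in% s1))
    }
})

test_that("egg-mass production recovers configured status means under truncation", {
  cfg <- synth_config(seed = 9, n_adults = 10000)
  pop <- generate_population(cfg)
  cts <- generate_eggmass_counts(pop, cfg)
  expect_true(all(cts$n_masses <= 8L))  # 4 cycles x cap 2
  for (st in c("paired", "solitary")) {
    x <- cts$n_masses[cts$social_status == st]
    target <- if (st == "paired") 1.57 else 0.81
    expect_lt(abs(mean(x) - target), 2 * sd(x) / sqrt(length(x)))
  }
  # no length effect -> no within-status correlation with shell length
  cfg0 <- synth_config(seed = 10, n_adults = 10000, length_effect_beta = 0)
  pop0 <- generate_population(cfg0)
  cts0 <- generate_eggmass_counts(pop0, cfg0)
  for (st in c("paired", "solitary")) {
    x <- cts0[cts0$social_status == st, ]
    expect_lt(abs(cor(x$n_masses, x$shell_length_mm)), 3 / sqrt(nrow(x)))
  }
})

test_that("conservative estimator never exceeds the true sire count", {
  cfg <- synth_config(seed = 17, n_adults = 60,
                      sires_per_mass_dist = c("1" = 0.4, "2" = 0.4,
                                              "3" = 0.2))
  r <- recovery_experiment(cfg, n_masses = 300)
  expect_true(r$never_overcount)
  # detection is conservative: estimated multi-paternity <= true fraction
  expect_lte(r$est$conservative, r$truth_freq)
})

test_that("recovery experiment reports zero extra-pair calls for a monogamous world", {
  cfg <- synth_config(seed = 23, prop_paired = 1, p_within_pair_use = 1,
                      p_extra_pair = 0, sires_per_mass_dist = c("1" = 1))
  r <- recovery_experiment(cfg, n_masses = 150)
  expect_equal(r$ep$estimated, 0)
  expect_equal(r$est$conservative, 0)
  expect_equal(r$truth_freq, 0)
})
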