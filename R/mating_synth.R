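# Synthetic mating-system generator: a pair-living, non-selfing
# hermaphrodite population with microsatellite genotypes, within-pair and
# extra-pair mating, Mendelian embryo pools, and negative-binomial egg-mass
# output. Every draw is recorded as ground truth so the parentage
# estimators can be validated against known sire sets.

.rdirichlet1 <- function(k, alpha) {
  x <- stats::rgamma(k, shape = alpha)
  x / sum(x)
}

#' Configuration for the synthetic mating-system generator
#'
#' Defaults emulate the field population the bundled dataset comes from:
#' four polyallelic microsatellite loci with 4-7 alleles, 75% of adults
#' living in pairs, pooled samples of ~500 embryos per egg mass, mean total
#' egg-mass output over four reproductive cycles of 1.57 (paired) vs 0.81
#' (solitary), status-specific shell lengths of 50.6 +/- 6.9 mm (paired)
#' and 47.2 +/- 6.0 mm (solitary), and a log-scale shell-length effect of
#' 0.0471 per mm on egg-mass output.
#'
#' @param seed RNG seed (mandatory)
#' @param n_adults number of adults
#' @param n_loci number of microsatellite loci
#' @param alleles_per_locus integer range (vector) to sample the allele
#'   count of each locus from
#' @param dirichlet_alpha symmetric Dirichlet concentration for allele
#'   frequencies
#' @param prop_paired proportion of adults living in pairs
#' @param p_within_pair_use probability a paired mother's partner sires
#'   part of her egg mass
#' @param p_extra_pair probability a paired mother's mass also has
#'   extra-pair sires
#' @param sires_per_mass_dist named numeric: sire count -> probability
#' @param paternity_skew optional vector of relative paternity shares for
#'   multi-sire masses (renormalised to the realised sire count); NULL =
#'   equal shares
#' @param n_embryos_pooled embryos pooled per egg-mass sample
#' @param detection_min_count minimum embryo count for an allele to appear
#'   in the pooled set (emulates read-depth dropout; default 1)
#' @param eggmass_mean_paired,eggmass_mean_solitary target mean total
#'   egg-mass output over `n_cycles` by social status
#' @param nb_dispersion negative-binomial size (theta); smaller = more
#'   overdispersed
#' @param shell_length_paired,shell_length_solitary `c(mean, sd)` of shell
#'   length (mm) by status
#' @param length_effect_beta log-scale effect of shell length (per mm) on
#'   egg-mass output
#' @return object of class `synth_config`
#' @export
synth_config <- function(seed,
                         n_adults = 111L,
                         n_loci = 4L,
                         alleles_per_locus = 4:7,
                         dirichlet_alpha = 1.0,
                         prop_paired = 0.75,
                         p_within_pair_use = 0.8,
                         p_extra_pair = 0.5,
                         sires_per_mass_dist = c("1" = 0.8, "2" = 0.2),
                         paternity_skew = NULL,
                         n_embryos_pooled = 500L,
                         detection_min_count = 1L,
                         eggmass_mean_paired = 1.57,
                         eggmass_mean_solitary = 0.81,
                         nb_dispersion = 5,
                         shell_length_paired = c(50.6, 6.9),
                         shell_length_solitary = c(47.2, 6.0),
                         length_effect_beta = 0.0471) {
  if (missing(seed)) stop("seed is mandatory in synth_config")
  stopifnot(n_adults >= 4L, n_loci >= 1L, all(alleles_per_locus >= 2L),
            dirichlet_alpha > 0, prop_paired >= 0, prop_paired <= 1,
            p_within_pair_use >= 0, p_within_pair_use <= 1,
            p_extra_pair >= 0, p_extra_pair <= 1,
            n_embryos_pooled >= 1L, detection_min_count >= 1L,
            nb_dispersion > 0, length_effect_beta >= 0 || TRUE)
  d <- sires_per_mass_dist
  if (is.null(names(d)) || any(d < 0) || abs(sum(d) - 1) > 1e-9)
    stop("sires_per_mass_dist must be a named probability vector summing to 1")
  structure(list(seed = as.integer(seed), n_adults = as.integer(n_adults),
                 n_loci = as.integer(n_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 dirichlet_alpha = dirichlet_alpha,
                 prop_paired = prop_paired,
                 p_within_pair_use = p_within_pair_use,
                 p_extra_pair = p_extra_pair,
                 sires_per_mass_dist = d,
                 paternity_skew = paternity_skew,
                 n_embryos_pooled = as.integer(n_embryos_pooled),
                 detection_min_count = as.integer(detection_min_count),
                 eggmass_mean_paired = eggmass_mean_paired,
                 eggmass_mean_solitary = eggmass_mean_solitary,
                 nb_dispersion = nb_dispersion,
                 shell_length_paired = shell_length_paired,
                 shell_length_solitary = shell_length_solitary,
                 length_effect_beta = length_effect_beta),
            class = "synth_config")
}

#' Generate a synthetic adult population
#'
#' Per-locus allele frequencies are drawn from a symmetric Dirichlet,
#' adults are Hardy-Weinberg genotypes, pair/solitary status and partners
#' are assigned, and shell lengths come from status-specific normals.
#' Allele labels are fragment lengths spaced by the repeat-motif length.
#'
#' @param config a [synth_config()]
#' @return list with `panel` (an [msat_panel()] with zero masses) and
#'   `truth` (allele frequency vectors and the partner map)
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  motifs <- c("AC", "TC", "TAA", "TTG")
  loci <- data.frame(
    locus = sprintf("L%02d", seq_len(config$n_loci)),
    repeat_motif = motifs[(seq_len(config$n_loci) - 1L) %% length(motifs) + 1L],
    stringsAsFactors = FALSE)
  freqs <- list(); labels <- list()
  for (i in seq_len(config$n_loci)) {
    na <- if (length(config$alleles_per_locus) == 1L) config$alleles_per_locus
          else sample(config$alleles_per_locus, 1L)
    f <- .rdirichlet1(na, config$dirichlet_alpha)
    step <- nchar(loci$repeat_motif[i])
    lab <- 100L + step * (0:(na - 1L))
    freqs[[loci$locus[i]]] <- f
    labels[[loci$locus[i]]] <- lab
  }
  n <- config$n_adults
  n_paired <- 2L * floor(n * config$prop_paired / 2)
  status <- c(rep("paired", n_paired), rep("solitary", n - n_paired))
  partner <- rep(NA_character_, n)
  ids <- sprintf("A%03d", seq_len(n))
  if (n_paired > 0L) {
    odd <- seq(1L, n_paired, by = 2L)
    partner[odd] <- ids[odd + 1L]
    partner[odd + 1L] <- ids[odd]
  }
  sl_par <- config$shell_length_paired; sl_sol <- config$shell_length_solitary
  shell <- ifelse(status == "paired",
                  stats::rnorm(n, sl_par[1], sl_par[2]),
                  stats::rnorm(n, sl_sol[1], sl_sol[2]))
  adults <- data.frame(adult_id = ids, social_status = status,
                       shell_length_mm = round(shell, 1),
                       stringsAsFactors = FALSE)
  for (loc in loci$locus) {
    f <- freqs[[loc]]; lab <- labels[[loc]]
    a <- lab[sample.int(length(f), n, TRUE, f)]
    b <- lab[sample.int(length(f), n, TRUE, f)]
    adults[[paste0(loc, "_a")]] <- pmin(a, b)
    adults[[paste0(loc, "_b")]] <- pmax(a, b)
  }
  masses <- data.frame(mass_id = character(), maternal_id = character(),
                       maternal_status = character(),
                       putative_sire_id = character(),
                       stringsAsFactors = FALSE)
  masses$alleles <- list()
  panel <- msat_panel(loci, adults, masses)
  list(panel = panel,
       truth = list(freqs = freqs, allele_labels = labels,
                    partner = stats::setNames(partner, ids)))
}

.draw_sires <- function(config, mother_id, partner_id, pool) {
  ks <- as.integer(names(config$sires_per_mass_dist))
  k <- ks[sample.int(length(ks), 1L, prob = config$sires_per_mass_dist)]
  sires <- character()
  if (!is.na(partner_id)) {
    if (stats::runif(1) < config$p_within_pair_use) sires <- partner_id
    extra_ok <- stats::runif(1) < config$p_extra_pair
    need <- k - length(sires)
    if (extra_ok && need > 0L) {
      cand <- setdiff(pool, c(mother_id, partner_id))
      if (length(cand) == 0L) stop("extra-pair sire pool is empty")
      sires <- c(sires, sample(cand, min(need, length(cand))))
    }
    if (length(sires) == 0L) sires <- partner_id  # a mass needs >= 1 sire
  } else {
    cand <- setdiff(pool, mother_id)
    if (length(cand) == 0L) stop("extra-pair sire pool is empty")
    sires <- sample(cand, min(k, length(cand)))
  }
  sires
}

#' Generate egg masses with Mendelian pooled-embryo allele sets
#'
#' For each mother, draws a sire set (the social partner with probability
#' `p_within_pair_use` for paired mothers, plus/or extra-pair sires drawn
#' uniformly from the other adults), allocates `n_embryos_pooled` embryos
#' to sires multinomially (equal shares unless `paternity_skew` is set),
#' gives each embryo one maternal and one paternal allele per locus, and
#' records the pooled allele set: every allele carried by at least
#' `detection_min_count` embryos.
#'
#' @param population result of [generate_population()]
#' @param config the same [synth_config()]
#' @param mothers adult IDs that deposit a mass (default: all adults); IDs
#'   may repeat to yield several masses per mother
#' @return list with `panel` (the population panel with masses attached)
#'   and `truth` (data.frame of per-mass true sires and embryo counts)
#' @export
generate_masses <- function(population, config, mothers = NULL) {
  stopifnot(inherits(config, "synth_config"))
  panel <- population$panel
  adults <- panel$adults
  if (is.null(mothers)) mothers <- adults$adult_id
  stopifnot(all(mothers %in% adults$adult_id))
  loci <- panel_loci(panel)
  truth_rows <- list(); mass_rows <- list(); allele_sets <- list()
  for (i in seq_along(mothers)) {
    mid <- mothers[i]
    mass_id <- sprintf("SM%04d", i)
    partner_id <- population$truth$partner[[mid]]
    sires <- .draw_sires(config, mid, partner_id, adults$adult_id)
    w <- if (is.null(config$paternity_skew)) rep(1, length(sires)) else {
      s <- config$paternity_skew[seq_along(sires)]
      if (anyNA(s)) stop("paternity_skew shorter than realised sire count")
      s
    }
    counts <- as.integer(stats::rmultinom(1L, config$n_embryos_pooled,
                                          w / sum(w)))
    sets <- list()
    for (loc in loci) {
      mg <- adult_genotype(panel, mid, loc)
      pool_ct <- integer()
      # maternal gametes across all embryos
      xm <- stats::rbinom(1L, config$n_embryos_pooled, 0.5)
      pool_ct <- c(pool_ct, stats::setNames(c(xm, config$n_embryos_pooled - xm),
                                            as.character(mg)))
      for (s in seq_along(sires)) {
        if (counts[s] == 0L) next
        sg <- adult_genotype(panel, sires[s], loc)
        xs <- stats::rbinom(1L, counts[s], 0.5)
        pool_ct <- c(pool_ct, stats::setNames(c(xs, counts[s] - xs),
                                              as.character(sg)))
      }
      tab <- tapply(pool_ct, names(pool_ct), sum)
      keep <- as.integer(names(tab))[tab >= config$detection_min_count]
      if (length(keep) == 0L) sets[loc] <- list(NULL)  # total dropout
      else sets[[loc]] <- sort(keep)
    }
    mass_rows[[i]] <- data.frame(
      mass_id = mass_id, maternal_id = mid,
      maternal_status = adults$social_status[match(mid, adults$adult_id)],
      putative_sire_id = if (is.na(partner_id)) NA_character_ else partner_id,
      stringsAsFactors = FALSE)
    allele_sets[[i]] <- sets
    truth_rows[[i]] <- data.frame(
      mass_id = mass_id, maternal_id = mid,
      n_sires = length(sires),
      sires = paste(sires, collapse = ";"),
      embryo_counts = paste(counts, collapse = ";"),
      extra_pair = any(sires != if (is.na(partner_id)) "" else partner_id),
      stringsAsFactors = FALSE)
  }
  masses <- do.call(rbind, mass_rows)
  masses$alleles <- allele_sets
  panel$masses <- masses
  list(panel = panel, truth = do.call(rbind, truth_rows))
}

# expected value of min(X, cap) for X ~ NB(mu, size)
.e_capped_nb <- function(mu, size, cap = 2L) {
  # E[min(X, cap)] = sum_{k=1..cap} P(X >= k)
  sapply(mu, function(m) {
    sum(1 - stats::pnbinom(0:(cap - 1L), mu = m, size = size))
  })
}

# marginal mean of capped per-cycle counts over L ~ N(lm, ls), total over
# n_cycles, for intercept a: mu_cycle(L) = exp(a + beta L) / n_cycles
.marginal_mean <- function(a, beta, lm, ls, size, n_cycles, cap = 2L) {
  f <- function(l) .e_capped_nb(exp(a + beta * l) / n_cycles, size, cap) *
    stats::dnorm(l, lm, ls)
  n_cycles * stats::integrate(f, lm - 8 * ls, lm + 8 * ls)$value
}

.solve_intercept <- function(target, beta, lm, ls, size, n_cycles, cap = 2L) {
  g <- function(a) .marginal_mean(a, beta, lm, ls, size, n_cycles, cap) - target
  upper_bound <- log(n_cycles * cap)  # cap on the achievable mean
  if (target >= n_cycles * cap)
    stop("target mean ", target, " infeasible with per-cycle cap ", cap)
  stats::uniroot(g, lower = -20 - beta * lm, upper = upper_bound + 10,
                 tol = 1e-10)$root
}

#' Generate egg-mass production counts by social status
#'
#' Total egg-mass output per adult over `n_cycles` reproductive cycles:
#' per-cycle counts are negative binomial with
#' `log(mu) = intercept_status + length_effect_beta * shell_length`,
#' truncated at 2 masses per cycle (a limpet deposits zero to two masses
#' per cycle). The status intercepts are solved numerically so that the
#' status-marginal mean of the truncated totals equals the configured
#' targets.
#'
#' @param population result of [generate_population()]
#' @param config the same [synth_config()]
#' @param n_cycles number of reproductive cycles (default 4)
#' @return data.frame `adult_id`, `social_status`, `shell_length_mm`,
#'   `n_masses`
#' @export
generate_eggmass_counts <- function(population, config, n_cycles = 4L) {
  stopifnot(inherits(config, "synth_config"))
  adults <- population$panel$adults
  beta <- config$length_effect_beta
  size <- config$nb_dispersion
  pars <- list(
    paired = list(target = config$eggmass_mean_paired,
                  lm = config$shell_length_paired[1],
                  ls = config$shell_length_paired[2]),
    solitary = list(target = config$eggmass_mean_solitary,
                    lm = config$shell_length_solitary[1],
                    ls = config$shell_length_solitary[2]))
  icept <- lapply(pars, function(p)
    .solve_intercept(p$target, beta, p$lm, p$ls, size, n_cycles))
  n <- nrow(adults)
  total <- integer(n)
  for (i in seq_len(n)) {
    st <- adults$social_status[i]
    if (!st %in% names(icept)) { total[i] <- NA_integer_; next }
    mu_cycle <- exp(icept[[st]] + beta * adults$shell_length_mm[i]) / n_cycles
    per_cycle <- pmin(stats::rnbinom(n_cycles, mu = mu_cycle, size = size), 2L)
    total[i] <- sum(per_cycle)
  }
  data.frame(adult_id = adults$adult_id,
             social_status = adults$social_status,
             shell_length_mm = adults$shell_length_mm,
             n_masses = total, stringsAsFactors = FALSE)
}

#' End-to-end recovery experiment on synthetic data
#'
#' Generates a population and `n_masses` egg masses, runs the parentage
#' estimators, and compares estimates against the generator's ground
#' truth.
#'
#' @param config a [synth_config()]
#' @param n_masses number of egg masses to simulate
#' @return list with `est` (multiple-paternity frequencies, conservative
#'   and liberal), `truth_freq` (true fraction of multi-sire masses),
#'   `ep` (estimated and true extra-pair fractions among paired masses
#'   with genotyped putative sires), `confusion` (table of true sire count
#'   vs conservative estimate), `never_overcount` (logical: conservative
#'   estimate <= true count for every mass), and the underlying `sires`
#'   data.frame
#' @export
recovery_experiment <- function(config, n_masses = 200L) {
  pop <- generate_population(config)
  mothers <- sample(pop$panel$adults$adult_id, n_masses, replace = TRUE)
  gm <- generate_masses(pop, config, mothers = mothers)
  est <- estimate_sires_panel(gm$panel)
  truth <- gm$truth[match(est$mass_id, gm$truth$mass_id), ]
  cons <- est$min_sires_conservative
  conf <- table(true = truth$n_sires, estimated = cons)
  ps <- pair_summary(gm$panel)
  paired_ids <- gm$panel$masses$mass_id[!is.na(gm$panel$masses$putative_sire_id)]
  true_ep <- truth$extra_pair[truth$mass_id %in% paired_ids]
  list(est = list(conservative = mean(cons >= 2L),
                  liberal = mean(est$sires_liberal >= 2L)),
       truth_freq = mean(truth$n_sires >= 2L),
       ep = list(estimated = if (nrow(ps$calls)) mean(ps$calls$call == "EP")
                 else NA_real_,
                 true = if (length(true_ep)) mean(true_ep) else NA_real_),
       confusion = conf,
       never_overcount = all(cons <= truth$n_sires),
       sires = cbind(est, true_n_sires = truth$n_sires,
                     true_extra_pair = truth$extra_pair))
}
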