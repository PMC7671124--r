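# Probability of detecting multiple paternity (PrDM) for a marker panel.
# Two detection models are supported:
#   "pooled":     the brood is observed only as the union of alleles per
#                 locus; multiple paternity is scored when some locus shows
#                 >= 3 non-maternal alleles (conservative heterozygous-sires
#                 rule, minimum sires >= 2). This matches inference from
#                 pooled-embryo genotyping.
#   "individual": every offspring is genotyped separately, so a paternal
#                 allele identical to a maternal one is still observable
#                 (e.g. through homozygous offspring); multiple paternity is
#                 scored when no single father genotype can explain the
#                 offspring array at some locus. This is the classical
#                 power model behind published PrDM tables, and is always
#                 >= the pooled-model power.

#' PrDM simulation configuration
#'
#' @param freqs list of `allele_freqs` objects or bare frequency vectors,
#'   one per locus
#' @param n_sires number of sires (>= 1)
#' @param skew vector of paternity shares, length `n_sires`, summing to 1
#' @param n_offspring embryos sampled and genotyped per brood
#' @param mother_known logical; the study design always knows the mother
#'   (default TRUE). With FALSE, detection uses the unknown-mother rule
#'   `max(0, |pool| - 2) >= 3` (pooled model only).
#' @param detection `"pooled"` (union of brood alleles only; default) or
#'   `"individual"` (offspring genotyped one by one, the classical PrDM
#'   power model)
#' @param n_replicates Monte Carlo replicates (default 20000)
#' @param seed RNG seed (mandatory for reproducibility)
#' @return object of class `prdm_config`
#' @export
prdm_config <- function(freqs, n_sires, skew = rep(1 / n_sires, n_sires),
                        n_offspring = 100L, mother_known = TRUE,
                        detection = c("pooled", "individual"),
                        n_replicates = 20000L, seed) {
  detection <- match.arg(detection)
  if (detection == "individual" && !isTRUE(mother_known))
    stop("the individual-offspring model requires a known mother")
  if (missing(seed)) stop("seed is mandatory in prdm_config")
  freqs <- lapply(freqs, function(f)
    if (inherits(f, "allele_freqs")) f$freqs else f)
  for (f in freqs)
    stopifnot(is.numeric(f), all(f > 0), abs(sum(f) - 1) < 1e-9)
  stopifnot(n_sires >= 1L, n_offspring >= 1L, n_replicates >= 1L)
  if (length(skew) != n_sires)
    stop("skew length (", length(skew), ") must equal n_sires (", n_sires, ")")
  if (any(skew < 0) || abs(sum(skew) - 1) > 1e-9)
    stop("skew entries must be >= 0 and sum to 1")
  structure(list(freqs = freqs, n_sires = as.integer(n_sires), skew = skew,
                 n_offspring = as.integer(n_offspring),
                 mother_known = isTRUE(mother_known),
                 detection = detection,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "prdm_config")
}

# alleles transmitted by one parent genotype to n offspring:
# returns the subset of the parent's alleles present among the n gametes
.transmitted <- function(genotype, n) {
  if (genotype[1] == genotype[2]) return(genotype[1])
  x <- stats::rbinom(1L, n, 0.5)  # gametes carrying allele 1
  if (x == n) genotype[1] else if (x == 0L) genotype[2] else genotype
}

.draw_genotype <- function(p) {
  sample(seq_along(p), 2L, replace = TRUE, prob = p)
}

#' Simulate one pooled brood
#'
#' Draws a Hardy-Weinberg mother and `n_sires` Hardy-Weinberg sires from
#' the panel frequencies, assigns each offspring to a sire by the skew
#' multinomial, gives every offspring one uniformly chosen maternal and one
#' paternal allele per locus, and pools: the observable per locus is the
#' union of offspring alleles.
#'
#' @param config a [prdm_config()] (its `seed`/`n_replicates` are ignored
#'   here; seed the session RNG yourself for reproducibility)
#' @return list with `mother` (per-locus genotype, allele indices),
#'   `sires` (list of per-locus genotypes), `sire_counts` (offspring per
#'   sire), and `pooled` (per-locus sorted union of offspring allele
#'   indices)
#' @export
simulate_brood <- function(config) {
  stopifnot(inherits(config, "prdm_config"))
  n_off <- config$n_offspring
  counts <- as.integer(stats::rmultinom(1L, n_off, config$skew))
  mother <- lapply(config$freqs, .draw_genotype)
  sires <- lapply(seq_len(config$n_sires), function(s)
    lapply(config$freqs, .draw_genotype))
  pooled <- lapply(seq_along(config$freqs), function(l) {
    mat <- .transmitted(mother[[l]], n_off)
    pat <- integer()
    for (s in seq_len(config$n_sires))
      if (counts[s] > 0L)
        pat <- c(pat, .transmitted(sires[[s]][[l]], counts[s]))
    sort(unique(c(mat, pat)))
  })
  names(pooled) <- names(config$freqs)
  list(mother = mother, sires = sires, sire_counts = counts, pooled = pooled)
}

.brood_detects <- function(brood, mother_known) {
  for (l in seq_along(brood$pooled)) {
    k <- if (mother_known)
      length(setdiff(brood$pooled[[l]], brood$mother[[l]]))
    else max(0L, length(brood$pooled[[l]]) - 2L)
    if (k >= 3L) return(TRUE)  # ceiling(k/2) >= 2
  }
  FALSE
}

#' Monte Carlo probability of detecting multiple paternity
#'
#' Fraction of replicate broods in which the conservative minimum-sires
#' rule infers two or more sires (some locus with >= 3 non-maternal
#' alleles). A single sire can never be detected as multiple, so
#' `n_sires = 1` returns exactly 0 without simulation.
#'
#' @param config a [prdm_config()]
#' @return object of class `prdm_result`: list with `prdm`, `mc_stderr`
#'   (binomial standard error), `n_replicates`
#' @export
prdm <- function(config) {
  stopifnot(inherits(config, "prdm_config"))
  if (config$n_sires == 1L)
    return(structure(list(prdm = 0, mc_stderr = 0,
                          n_replicates = config$n_replicates),
                     class = "prdm_result"))
  set.seed(config$seed)
  R <- config$n_replicates
  n_off <- config$n_offspring
  # replicate-shared offspring-to-sire assignment, columns = replicates
  counts <- stats::rmultinom(R, n_off, config$skew)
  detect <- rep(FALSE, R)
  for (p in config$freqs) {
    k <- length(p)
    if (k > 30L) stop("more than 30 alleles at one locus is unsupported")
    bit <- bitwShiftL(1L, 0:(k - 1))
    # allele-presence bitmasks, one integer per replicate
    mask_of <- function(gA, gB, n) {
      # transmitted alleles of a parent with genotype (gA, gB) over n gametes
      x <- stats::rbinom(R, n, 0.5)
      bitwOr(ifelse(x > 0L, bit[gA], 0L), ifelse(x < n, bit[gB], 0L))
    }
    momA <- sample.int(k, R, TRUE, p); momB <- sample.int(k, R, TRUE, p)
    mom_mask <- bitwOr(bit[momA], bit[momB])
    if (config$detection == "pooled") {
      pat_mask <- integer(R)
      for (s in seq_len(config$n_sires)) {
        gA <- sample.int(k, R, TRUE, p); gB <- sample.int(k, R, TRUE, p)
        pat_mask <- bitwOr(pat_mask, mask_of(gA, gB, counts[s, ]))
      }
      target <- if (config$mother_known) {
        bitwAnd(pat_mask, bitwNot(mom_mask))   # non-maternal alleles
      } else {
        bitwOr(pat_mask, mask_of(momA, momB, rep(n_off, R)))  # full pool
      }
      cnt <- integer(R)
      for (b in bit) cnt <- cnt + (bitwAnd(target, b) != 0L)
      if (!config$mother_known) cnt <- pmax(cnt - 2L, 0L)
      detect <- detect | (cnt >= 3L)
    } else {
      # individual-offspring model. Each offspring is (maternal, paternal)
      # allele pair. A paternal allele f is "determined" when some embryo
      # makes it unambiguous: any embryo if f is non-maternal, or an
      # embryo whose maternal draw equals f (a homozygote) if f is
      # maternal. The only ambiguous evidence class is an embryo carrying
      # both alleles of a heterozygous mother. No single father explains
      # the array iff >= 3 determined paternal alleles, or exactly 2 that
      # are both non-maternal while the ambiguous class also occurred.
      mom_het <- momA != momB
      det_mask <- integer(R)   # determined paternal alleles
      amb <- rep(FALSE, R)     # ambiguous {m1,m2} class seen
      add_allele <- function(f, n_f, det_mask, amb) {
        # n_f embryos carry paternal allele f; split their maternal draws
        c1 <- stats::rbinom(R, n_f, 0.5)      # embryos with maternal momA
        c2 <- n_f - c1
        is_m1 <- f == momA; is_m2 <- f == momB
        det <- ifelse(!is_m1 & !is_m2, n_f > 0L,
                      ifelse(!mom_het, n_f > 0L,
                             ifelse(is_m1, c1 > 0L, c2 > 0L)))
        amb_f <- mom_het & ((is_m1 & c2 > 0L) | (is_m2 & c1 > 0L))
        list(det_mask = bitwOr(det_mask, ifelse(det, bit[f], 0L)),
             amb = amb | amb_f)
      }
      for (s in seq_len(config$n_sires)) {
        n_s <- counts[s, ]
        gA <- sample.int(k, R, TRUE, p); gB <- sample.int(k, R, TRUE, p)
        nA <- ifelse(gA == gB, n_s, stats::rbinom(R, n_s, 0.5))
        st <- add_allele(gA, nA, det_mask, amb)
        st <- add_allele(gB, n_s - nA, st$det_mask, st$amb)
        det_mask <- st$det_mask; amb <- st$amb
      }
      cnt <- integer(R)
      for (b in bit) cnt <- cnt + (bitwAnd(det_mask, b) != 0L)
      nonmat_only <- bitwAnd(det_mask, mom_mask) == 0L
      detect <- detect | (cnt >= 3L) | (cnt == 2L & amb & nonmat_only)
    }
  }
  pr <- mean(detect)
  structure(list(prdm = pr,
                 mc_stderr = sqrt(pr * (1 - pr) / R),
                 n_replicates = R),
            class = "prdm_result")
}

#' @export
print.prdm_result <- function(x, ...) {
  cat(sprintf("PrDM = %.4f (MC SE %.4f, %d replicates)\n",
              x$prdm, x$mc_stderr, x$n_replicates))
  invisible(x)
}

# integer compositions of n into k ordered parts
.compositions <- function(n, k) {
  if (k == 1L) return(list(n))
  out <- list()
  for (i in 0:n)
    for (rest in .compositions(n - i, k - 1L))
      out[[length(out) + 1L]] <- c(i, rest)
  out
}

# distribution of the transmitted-allele subset for one parent genotype
# over n offspring: list of (set, prob)
.transmitted_dist <- function(genotype, n) {
  if (n == 0L) return(list(list(set = integer(), pr = 1)))
  if (genotype[1] == genotype[2])
    return(list(list(set = genotype[1], pr = 1)))
  h <- 0.5^n
  list(list(set = genotype[1], pr = h),
       list(set = genotype[2], pr = h),
       list(set = sort(genotype), pr = 1 - 2 * h))
}

# P(single-locus non-detection | offspring-per-sire counts), pooled model
.lfail_pooled <- function(p, counts) {
  gts <- .hwe_genotypes(p)
  active <- which(counts > 0L)
  fail <- 0
  rec <- function(s_idx, sets_so_far, pr_so_far, mom) {
    if (pr_so_far == 0) return()
    if (s_idx > length(active)) {
      nonmat <- setdiff(unique(unlist(sets_so_far)), mom$g)
      if (length(nonmat) <= 2L) fail <<- fail + pr_so_far
      return()
    }
    s <- active[s_idx]
    for (sire in gts)
      for (td in .transmitted_dist(sire$g, counts[s]))
        rec(s_idx + 1L, c(sets_so_far, list(td$set)),
            pr_so_far * sire$pr * td$pr, mom)
  }
  for (mom in gts) rec(1L, list(), mom$pr, mom)
  fail
}

# P(single-locus non-detection | counts), individual-offspring model.
# Evidence of one embryo = its set of possible paternal alleles given the
# mother; the array is explainable by a single father iff some allele pair
# intersects every evidence set (2-element hitting set).
.lfail_individual <- function(p, counts) {
  k <- length(p)
  gts <- .hwe_genotypes(p)
  pairs <- list()
  for (x in seq_len(k)) for (y in x:k) pairs[[length(pairs) + 1L]] <- c(x, y)
  active <- which(counts > 0L)
  pset <- function(o, M) {
    s <- integer()
    if (o[2] %in% M) s <- c(s, o[1])
    if (o[1] %in% M) s <- c(s, o[2])
    sort(unique(s))
  }
  fail <- 0
  for (mom in gts) {
    M <- mom$g
    # per sire: distribution over the set of realized evidence classes
    per_sire <- lapply(active, function(s) {
      n_s <- counts[s]
      states <- list()  # list of list(sets = list of evidence sets, pr)
      for (sire in gts) {
        # embryo evidence classes for this sire: 4 equiprobable draws
        cls <- list(); q <- numeric()
        for (m in M) for (f in sire$g) {
          ev <- pset(sort(c(m, f)), M)
          hit <- FALSE
          for (ci in seq_along(cls))
            if (identical(cls[[ci]], ev)) { q[ci] <- q[ci] + 0.25; hit <- TRUE }
          if (!hit) { cls[[length(cls) + 1L]] <- ev; q <- c(q, 0.25) }
        }
        # P(realized class subset == T) by inclusion-exclusion
        nc <- length(cls)
        for (tmask in seq_len(2^nc) - 1L) {
          Tidx <- which(bitwAnd(tmask, bitwShiftL(1L, seq_len(nc) - 1L)) > 0L)
          if (length(Tidx) == 0L) next
          pr_T <- 0
          for (smask in seq_len(2^length(Tidx)) - 1L) {
            Sidx <- Tidx[bitwAnd(smask,
                                 bitwShiftL(1L, seq_along(Tidx) - 1L)) > 0L]
            pr_T <- pr_T + (-1)^(length(Tidx) - length(Sidx)) *
              sum(q[Sidx])^n_s
          }
          if (pr_T <= 0) next
          states[[length(states) + 1L]] <-
            list(sets = cls[Tidx], pr = sire$pr * pr_T)
        }
      }
      states
    })
    # cross-combine sires, then test single-father explainability
    combos <- list(list(sets = list(), pr = 1))
    for (st in per_sire) {
      nxt <- list()
      for (a in combos) for (b in st)
        nxt[[length(nxt) + 1L]] <- list(sets = c(a$sets, b$sets),
                                        pr = a$pr * b$pr)
      combos <- nxt
    }
    for (cb in combos) {
      explainable <- any(vapply(pairs, function(xy)
        all(vapply(cb$sets, function(ev) any(ev %in% xy), logical(1))),
        logical(1)))
      if (explainable) fail <- fail + mom$pr * cb$pr
    }
  }
  fail
}

#' Exact PrDM by exhaustive enumeration
#'
#' Ground-truth oracle for [prdm()] on tiny configurations: sums over all
#' multinomial offspring-to-sire assignments (shared across loci) and, per
#' locus, over every mother genotype, sire genotype combination, and
#' transmission pattern, weighting each by its probability. For the
#' individual-offspring model, per-embryo evidence (the set of paternal
#' alleles that could explain the embryo) is enumerated and a brood is
#' undetected when a 2-allele hitting set — a single father genotype —
#' covers every evidence set. Refuses configurations whose state space
#' exceeds `max_states` (default 1e7) with a size estimate.
#'
#' @param config a [prdm_config()]; only `mother_known = TRUE` is supported
#' @param max_states refusal threshold on the enumeration size
#' @return exact detection probability (numeric scalar)
#' @export
prdm_exact <- function(config, max_states = 1e7) {
  stopifnot(inherits(config, "prdm_config"))
  if (!config$mother_known)
    stop("prdm_exact supports known mothers only")
  if (config$n_sires == 1L) return(0)
  n_gt <- vapply(config$freqs, function(p)
    length(p) * (length(p) + 1) / 2, numeric(1))
  comps <- .compositions(config$n_offspring, config$n_sires)
  est <- sum(n_gt * n_gt^config$n_sires *
               (2^4)^config$n_sires) * length(comps)
  if (est > max_states)
    stop("state space too large for exact enumeration (~", format(est),
         " states > ", format(max_states), ")")
  lfail <- if (config$detection == "pooled") .lfail_pooled else
    .lfail_individual
  # P(no locus detects) = sum over assignments n of P(n) * prod_l P_fail_l(n)
  p_nodetect <- 0
  for (cnt in comps) {
    pr_cnt <- stats::dmultinom(cnt, prob = config$skew)
    if (pr_cnt == 0) next
    p_nodetect <- p_nodetect +
      pr_cnt * prod(vapply(config$freqs, lfail, numeric(1), counts = cnt))
  }
  1 - p_nodetect
}

#' PrDM over a table of sire-number / skew scenarios
#'
#' @param freqs per-locus allele frequencies (as in [prdm_config()])
#' @param scenarios list of scenarios, each a list/vector with `n_sires`
#'   and `skew` (paternity shares)
#' @param n_offspring embryos genotyped per brood (default 100)
#' @param detection detection model, as in [prdm_config()]
#' @param n_replicates Monte Carlo replicates per scenario
#' @param seed base RNG seed; scenario i uses `seed + i`
#' @return data.frame with columns `n_sires`, `skew`, `prdm`, `mc_stderr`
#' @examples
#' p <- sgigas_panel()
#' fr <- lapply(panel_loci(p), function(l) allele_frequencies(p$adults, l))
#' prdm_table(fr, list(list(n_sires = 2, skew = c(0.5, 0.5))),
#'            n_replicates = 500, seed = 1)
#' @export
prdm_table <- function(freqs, scenarios, n_offspring = 100L,
                       detection = c("pooled", "individual"),
                       n_replicates = 20000L, seed) {
  detection <- match.arg(detection)
  if (missing(seed)) stop("seed is mandatory")
  if (length(scenarios) == 0L)
    return(data.frame(n_sires = integer(), skew = character(),
                      prdm = numeric(), mc_stderr = numeric(),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_along(scenarios), function(i) {
    sc <- scenarios[[i]]
    cfg <- prdm_config(freqs, n_sires = sc$n_sires, skew = sc$skew,
                       n_offspring = n_offspring, detection = detection,
                       n_replicates = n_replicates, seed = seed + i)
    res <- prdm(cfg)
    data.frame(n_sires = sc$n_sires,
               skew = paste(round(100 * sc$skew, 1), collapse = ":"),
               prdm = res$prdm, mc_stderr = res$mc_stderr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
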