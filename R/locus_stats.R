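# Panel diagnostics: the per-locus summary statistics (heterozygosities,
# HWE, null alleles, exclusion probabilities) used to judge whether a
# microsatellite panel is fit for parentage analysis.

.locus_calls <- function(adults, locus) {
  a <- adults[[paste0(locus, "_a")]]
  b <- adults[[paste0(locus, "_b")]]
  if (is.null(a) || is.null(b)) stop("no genotype columns for locus ", locus)
  keep <- !is.na(a) & !is.na(b)
  cbind(a = a[keep], b = b[keep])
}

#' Allele frequencies at one locus
#'
#' Straight gene-counting estimate: each typed adult contributes two
#' alleles; adults not genotyped at the locus are excluded.
#'
#' @param adults adult genotype data.frame (the `adults` element of an
#'   [msat_panel()]), with `<locus>_a`/`<locus>_b` columns
#' @param locus locus name
#' @return object of class `allele_freqs`: list with `locus`, `freqs`
#'   (named numeric, sums to 1), `n_typed`.
#' @export
allele_frequencies <- function(adults, locus) {
  g <- .locus_calls(adults, locus)
  if (nrow(g) == 0L) stop("no data at locus ", locus)
  tab <- table(c(g[, "a"], g[, "b"]))
  freqs <- as.numeric(tab) / sum(tab)
  names(freqs) <- names(tab)
  structure(list(locus = locus, freqs = freqs, n_typed = nrow(g)),
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat("<allele_freqs> locus ", x$locus, ", N = ", x$n_typed, "\n", sep = "")
  print(round(x$freqs, 4))
  invisible(x)
}

#' Observed and expected heterozygosity
#'
#' `Ho` is the fraction of typed adults carrying two distinct alleles.
#' `He` is Nei's unbiased estimator \eqn{\frac{2N}{2N-1}(1 - \sum p_i^2)}.
#'
#' @inheritParams allele_frequencies
#' @return named numeric `c(Ho=, He=)`
#' @export
heterozygosities <- function(adults, locus) {
  g <- .locus_calls(adults, locus)
  n <- nrow(g)
  if (n < 2L) stop("unbiased He needs at least 2 typed adults at ", locus)
  ho <- mean(g[, "a"] != g[, "b"])
  p <- allele_frequencies(adults, locus)$freqs
  he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  c(Ho = ho, He = he)
}

#' Chi-square goodness-of-fit test for Hardy-Weinberg equilibrium
#'
#' Observed genotype counts are compared with their Hardy-Weinberg
#' expectations computed from the sample allele frequencies. Genotype
#' classes with expected count below `min_expected` are pooled, lowest
#' first, into a single rare class until every class meets the threshold.
#' Degrees of freedom are `classes - alleles`, floored at 1, and the Yates
#' continuity correction is applied when df = 1. The returned p-value is
#' uncorrected; panel-wide Bonferroni adjustment is done by
#' [panel_summary()].
#'
#' @inheritParams allele_frequencies
#' @param min_expected minimum expected count per genotype class before
#'   pooling (default 1)
#' @return list with `chi2`, `df`, `p` (`NA` with `chi2 = NA` when fewer
#'   than two classes remain after pooling)
#' @export
hwe_test <- function(adults, locus, min_expected = 1.0) {
  g <- .locus_calls(adults, locus)
  n <- nrow(g)
  if (n < 5L) stop("HWE test needs at least 5 typed adults at ", locus)
  p <- allele_frequencies(adults, locus)$freqs
  alleles <- names(p)
  k <- length(p)
  # all unordered genotype classes
  cls <- list(); exp_ct <- c(); obs_ct <- c()
  geno_key <- paste(pmin(g[, "a"], g[, "b"]), pmax(g[, "a"], g[, "b"]))
  for (i in seq_len(k)) for (j in i:k) {
    e <- if (i == j) n * p[i]^2 else 2 * n * p[i] * p[j]
    o <- sum(geno_key == paste(min(as.integer(alleles[c(i, j)])),
                               max(as.integer(alleles[c(i, j)]))))
    cls[[length(cls) + 1L]] <- c(alleles[i], alleles[j])
    exp_ct <- c(exp_ct, e); obs_ct <- c(obs_ct, o)
  }
  # pool lowest-expected classes into one rare class
  ord <- order(exp_ct)
  exp_ct <- exp_ct[ord]; obs_ct <- obs_ct[ord]
  n_pool <- 0L
  repeat {
    rest_e <- exp_ct[-seq_len(n_pool)]
    pool_e <- sum(exp_ct[seq_len(n_pool)])
    if ((n_pool == 0L || pool_e >= min_expected) &&
        (length(rest_e) == 0L || min(rest_e) >= min_expected)) break
    n_pool <- n_pool + 1L
    if (n_pool >= length(exp_ct)) break
  }
  if (n_pool > 0L) {
    e_final <- c(sum(exp_ct[seq_len(n_pool)]), exp_ct[-seq_len(n_pool)])
    o_final <- c(sum(obs_ct[seq_len(n_pool)]), obs_ct[-seq_len(n_pool)])
  } else {
    e_final <- exp_ct; o_final <- obs_ct
  }
  if (length(e_final) < 2L)
    return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_))
  df <- max(length(e_final) - k, 1L)
  dev <- abs(o_final - e_final)
  if (df == 1L) dev <- pmax(dev - 0.5, 0)  # Yates continuity correction
  chi2 <- sum(dev^2 / e_final)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Null-allele frequency from homozygote excess
#'
#' Closed-form moment estimator `(He - Ho) / (He + Ho)`: a non-amplifying
#' allele hides heterozygotes as apparent homozygotes, so homozygote excess
#' measures its frequency. Negative values indicate heterozygote excess.
#'
#' @inheritParams allele_frequencies
#' @return numeric estimate in (-1, 1)
#' @export
null_allele_frequency <- function(adults, locus) {
  h <- heterozygosities(adults, locus)
  if (h[["He"]] + h[["Ho"]] == 0) {
    warning("He + Ho = 0 at locus ", locus, "; returning 0")
    return(0)
  }
  unname((h[["He"]] - h[["Ho"]]) / (h[["He"]] + h[["Ho"]]))
}

# ---- exclusion probabilities --------------------------------------------

# unordered genotype list with HWE probabilities for a frequency vector
.hwe_genotypes <- function(p) {
  k <- length(p)
  out <- list()
  for (i in seq_len(k)) for (j in i:k)
    out[[length(out) + 1L]] <- list(g = c(i, j),
                                    pr = if (i == j) p[i]^2 else 2 * p[i] * p[j])
  out
}

#' Parentage exclusion probabilities for one locus
#'
#' Operational definitions, for a random Hardy-Weinberg mother-father pair,
#' their Mendelian offspring, and a random unrelated Hardy-Weinberg
#' candidate:
#' \describe{
#'   \item{P1 (no parent known)}{probability the candidate shares no allele
#'     with the offspring, i.e. is excluded as a parent on the offspring
#'     genotype alone.}
#'   \item{P2 (one parent known)}{probability the candidate cannot supply
#'     any allele the offspring must have received from its second parent,
#'     given the true mother's genotype.}
#' }
#' Closed form: with offspring genotype \eqn{\{a,b\}} Hardy-Weinberg
#' distributed, \eqn{P1 = \sum_g HWE(g) (1 - p_a - p_b)^2}; P2 sums over
#' mother genotype, transmitted maternal allele and paternal allele, with
#' the candidate excluded when it carries none of the alleles that could
#' complete the offspring genotype paternally. [exclusion_probabilities_enum()]
#' recomputes both by brute-force enumeration and must agree to 1e-12.
#'
#' @param freqs an `allele_freqs` object, or a bare numeric frequency
#'   vector summing to 1
#' @return named numeric `c(P1=, P2=)`; a fixed single-allele locus gives
#'   `c(0, 0)`.
#' @export
exclusion_probabilities <- function(freqs) {
  p <- if (inherits(freqs, "allele_freqs")) freqs$freqs else freqs
  stopifnot(is.numeric(p), all(p > 0), abs(sum(p) - 1) < 1e-9)
  p <- unname(p)
  k <- length(p)
  if (k == 1L) return(c(P1 = 0, P2 = 0))
  # P1: offspring of random HWE parents is itself HWE distributed
  p1 <- 0
  for (i in seq_len(k)) {
    p1 <- p1 + p[i]^2 * (1 - p[i])^2
    if (i < k) for (j in (i + 1):k)
      p1 <- p1 + 2 * p[i] * p[j] * (1 - p[i] - p[j])^2
  }
  # P2: sum over mother genotype (i,j), transmitted maternal allele m,
  # paternal allele f. Required paternal set S: if mother carries both
  # offspring alleles, either could be paternal; otherwise only f.
  p2 <- 0
  for (i in seq_len(k)) for (j in i:k) {
    pr_mom <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
    for (m in unique(c(i, j))) {
      pr_m <- if (i == j) 1 else 0.5
      for (f in seq_len(k)) {
        # offspring {m, f}; S = paternal alleles a candidate must lack
        if (f %in% c(i, j)) S <- unique(c(m, f)) else S <- f
        p2 <- p2 + pr_mom * pr_m * p[f] * (1 - sum(p[S]))^2
      }
    }
  }
  c(P1 = p1, P2 = p2)
}

#' Exclusion probabilities by exhaustive enumeration
#'
#' Independent oracle for [exclusion_probabilities()]: enumerates every
#' (mother, father, offspring, candidate) genotype combination weighted by
#' Hardy-Weinberg probabilities and Mendelian segregation, and applies
#' generic set logic — a candidate is compatible as sole stated parent when
#' it shares an allele with the offspring (P1), and compatible as second
#' parent when some maternal/candidate allele pair reconstitutes the
#' offspring genotype (P2).
#'
#' @inheritParams exclusion_probabilities
#' @return named numeric `c(P1=, P2=)`
#' @export
exclusion_probabilities_enum <- function(freqs) {
  p <- if (inherits(freqs, "allele_freqs")) freqs$freqs else freqs
  stopifnot(is.numeric(p), all(p > 0), abs(sum(p) - 1) < 1e-9)
  p <- unname(p)
  if (length(p) == 1L) return(c(P1 = 0, P2 = 0))
  gts <- .hwe_genotypes(p)
  A1 <- vapply(gts, function(g) g$g[1], numeric(1))
  A2 <- vapply(gts, function(g) g$g[2], numeric(1))
  W <- vapply(gts, function(g) g$pr, numeric(1))
  p1 <- 0; p2 <- 0
  for (mom in gts) for (dad in gts) {
    w_pair <- mom$pr * dad$pr
    for (mi in 1:2) for (fi in 1:2) {
      o1 <- min(mom$g[mi], dad$g[fi]); o2 <- max(mom$g[mi], dad$g[fi])
      w_off <- w_pair * 0.25
      # candidates sharing no allele with the offspring (vector over all
      # candidate genotypes)
      p1 <- p1 + w_off * sum(W[A1 != o1 & A1 != o2 & A2 != o1 & A2 != o2])
      # candidate can be the second parent iff mother supplies one
      # offspring allele and the candidate the other
      mom_o1 <- o1 %in% mom$g; mom_o2 <- o2 %in% mom$g
      cand_o1 <- A1 == o1 | A2 == o1; cand_o2 <- A1 == o2 | A2 == o2
      compat <- (mom_o1 & cand_o2) | (mom_o2 & cand_o1)
      p2 <- p2 + w_off * sum(W[!compat])
    }
  }
  c(P1 = p1, P2 = p2)
}

#' Combine per-locus exclusion probabilities across a panel
#'
#' Independent loci each get a chance to exclude, so the combined
#' probability is \eqn{1 - \prod_l (1 - P_l)}.
#'
#' @param p numeric vector of per-locus exclusion probabilities
#' @return combined exclusion probability
#' @export
combine_exclusion <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  1 - prod(1 - p)
}

#' Per-locus summary statistics and combined exclusion probabilities
#'
#' One row per locus with allele count, sample size, heterozygosities, the
#' Hardy-Weinberg p-value (raw and Bonferroni-adjusted across the panel),
#' null-allele frequency, and both exclusion probabilities; plus the
#' combined exclusion probabilities over all loci. Per-locus failures
#' become NA rows rather than aborting the panel.
#'
#' @param adults adult genotype data.frame
#' @param loci character vector of locus names (or the `loci` data.frame of
#'   a panel)
#' @param min_expected passed to [hwe_test()]
#' @return object of class `locus_panel_summary`: list with `summary`
#'   data.frame and `combined` (named numeric, `no_parent` / `one_parent`)
#' @examples
#' p <- sgigas_panel()
#' panel_summary(p$adults, panel_loci(p))
#' @export
panel_summary <- function(adults, loci, min_expected = 1.0) {
  if (is.data.frame(loci)) loci <- loci$locus
  stopifnot(length(loci) >= 1L)
  rows <- lapply(loci, function(loc) {
    out <- data.frame(locus = loc, Na = NA_integer_, N = NA_integer_,
                      Ho = NA_real_, He = NA_real_, hwe_p = NA_real_,
                      hwe_p_bonf = NA_real_, Fnull = NA_real_,
                      Pexcl_no_parent = NA_real_,
                      Pexcl_one_parent = NA_real_, stringsAsFactors = FALSE)
    tryCatch({
      af <- allele_frequencies(adults, loc)
      out$Na <- length(af$freqs); out$N <- af$n_typed
      h <- heterozygosities(adults, loc)
      out$Ho <- h[["Ho"]]; out$He <- h[["He"]]
      out$hwe_p <- hwe_test(adults, loc, min_expected)$p
      out$Fnull <- null_allele_frequency(adults, loc)
      pe <- exclusion_probabilities(af)
      out$Pexcl_no_parent <- pe[["P1"]]
      out$Pexcl_one_parent <- pe[["P2"]]
      out
    }, error = function(e) out)
  })
  tab <- do.call(rbind, rows)
  tab$hwe_p_bonf <- pmin(tab$hwe_p * length(loci), 1)
  ok <- !is.na(tab$Pexcl_no_parent)
  combined <- c(no_parent = combine_exclusion(tab$Pexcl_no_parent[ok]),
                one_parent = combine_exclusion(tab$Pexcl_one_parent[ok]))
  structure(list(summary = tab, combined = combined),
            class = "locus_panel_summary")
}

#' @export
print.locus_panel_summary <- function(x, digits = 3, ...) {
  tab <- x$summary
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  cat(sprintf("Combined exclusion: %.3f (no parent known), %.3f (one parent known)\n",
              x$combined[["no_parent"]], x$combined[["one_parent"]]))
  invisible(x)
}
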