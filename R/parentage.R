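# Minimum-sires estimation and monogamy / extra-pair classification from
# pooled-brood allele sets.

#' Count non-maternal alleles in a pooled brood allele set
#'
#' With a known mother, every allele of the pool not carried by her must
#' have come from a sire. With an unknown mother the two most-explaining
#' alleles are assumed maternal, so the count is `max(0, |set| - 2)`.
#'
#' @param alleles integer vector of pooled alleles at one locus, or `NULL`
#'   for no data
#' @param maternal integer vector of the mother's two alleles, or `NULL`
#'   when the mother is unknown/unsampled
#' @return integer count, or `NA` when the locus has no data
#' @export
nonmaternal_alleles <- function(alleles, maternal = NULL) {
  if (is.null(alleles)) return(NA_integer_)
  stopifnot(length(alleles) >= 1L)
  if (is.null(maternal)) return(max(0L, length(unique(alleles)) - 2L))
  length(setdiff(alleles, maternal))
}

#' Estimate the minimum number of sires of one egg mass
#'
#' Per locus, let k be the number of non-maternal alleles. Assuming every
#' sire is heterozygous gives the conservative per-locus minimum
#' `ceiling(k / 2)`; assuming every sire is homozygous gives the liberal
#' estimate `k`. The mass-level estimates are the maximum over informative
#' loci (sires seen at different loci are not additive evidence), floored
#' at 1 — a brood always has at least one sire.
#'
#' @param mass one row of a panel's `masses` table (a list or data.frame
#'   row with `mass_id` and `alleles`), or a named list of per-locus allele
#'   vectors
#' @param mother integer-pair genotype list keyed by locus, or `NULL` for an
#'   unknown mother; alternatively pass `panel` and identifiers via
#'   [estimate_sires_panel()]
#' @param loci character vector of loci to consider (defaults to the names
#'   of the mass allele sets)
#' @return object of class `sire_estimate`: list with `mass_id`,
#'   `per_locus_nonmaternal` (named integer, NA where no data),
#'   `min_sires_conservative`, `sires_liberal`, `maternal_known`
#' @export
estimate_sires <- function(mass, mother = NULL, loci = NULL) {
  if (!is.null(mass$alleles) && is.list(mass$alleles) &&
      !is.null(mass$mass_id)) {
    sets <- if (is.data.frame(mass)) mass$alleles[[1L]] else mass$alleles
    mass_id <- as.character(mass$mass_id)
  } else {
    sets <- mass
    mass_id <- NA_character_
  }
  if (is.null(loci)) loci <- names(sets)
  k <- vapply(loci, function(loc) {
    mg <- if (is.null(mother)) NULL else mother[[loc]]
    nonmaternal_alleles(sets[[loc]], mg)
  }, integer(1))
  if (all(is.na(k))) stop("uninformative mass: no locus has data",
                          if (!is.na(mass_id)) paste0(" (mass ", mass_id, ")"))
  cons <- max(1L, max(ceiling(k / 2), na.rm = TRUE))
  lib <- max(1L, max(k, na.rm = TRUE))
  structure(list(mass_id = mass_id, per_locus_nonmaternal = k,
                 min_sires_conservative = as.integer(cons),
                 sires_liberal = as.integer(lib),
                 maternal_known = !is.null(mother)),
            class = "sire_estimate")
}

#' @export
print.sire_estimate <- function(x, ...) {
  cat("<sire_estimate> mass ", x$mass_id,
      if (!x$maternal_known) " (mother unknown)", "\n",
      "  non-maternal per locus: ",
      paste(names(x$per_locus_nonmaternal), x$per_locus_nonmaternal,
            sep = "=", collapse = ", "), "\n",
      "  min sires: ", x$min_sires_conservative, " (conservative), ",
      x$sires_liberal, " (liberal)\n", sep = "")
  invisible(x)
}

.mother_genotypes <- function(panel, maternal_id) {
  if (is.na(maternal_id)) return(NULL)
  g <- lapply(panel_loci(panel), function(loc)
    adult_genotype(panel, maternal_id, loc))
  names(g) <- panel_loci(panel)
  if (all(vapply(g, is.null, logical(1)))) NULL else g
}

#' Sire estimates for every egg mass in a panel
#'
#' @param panel an `msat_panel`
#' @return data.frame with one row per mass: `mass_id`, `maternal_known`,
#'   `min_sires_conservative`, `sires_liberal`, and one `nonmat_<locus>`
#'   column per locus
#' @export
estimate_sires_panel <- function(panel) {
  stopifnot(nrow(panel$masses) >= 1L)
  rows <- lapply(seq_len(nrow(panel$masses)), function(i) {
    m <- panel$masses[i, ]
    est <- estimate_sires(m, .mother_genotypes(panel, m$maternal_id),
                          loci = panel_loci(panel))
    out <- data.frame(mass_id = est$mass_id,
                      maternal_known = est$maternal_known,
                      min_sires_conservative = est$min_sires_conservative,
                      sires_liberal = est$sires_liberal,
                      stringsAsFactors = FALSE)
    for (loc in panel_loci(panel))
      out[[paste0("nonmat_", loc)]] <- est$per_locus_nonmaternal[[loc]]
    out
  })
  do.call(rbind, rows)
}

#' Frequency of multiple paternity across a panel
#'
#' @param panel an `msat_panel`
#' @param mode `"conservative"` (heterozygous-sires rule) or `"liberal"`
#'   (homozygous-sires rule)
#' @return list with `n_multiple`, `n_total`, `frequency`
#' @export
count_multiple_paternity <- function(panel,
                                     mode = c("conservative", "liberal")) {
  mode <- match.arg(mode)
  est <- estimate_sires_panel(panel)
  n_sires <- if (mode == "conservative") est$min_sires_conservative else
    est$sires_liberal
  n_mult <- sum(n_sires >= 2L)
  list(n_multiple = n_mult, n_total = nrow(est),
       frequency = n_mult / nrow(est))
}

#' Classify one paired egg mass as monogamous or extra-pair
#'
#' A brood is consistent with sexual monogamy (MO) when every pooled allele
#' at every locus occurs in the mother or her social partner (the putative
#' sire); one allele outside that union at any locus is evidence of an
#' extra-pair sire (EP). When the putative sire was never genotyped the
#' call is UNDETERMINED.
#'
#' Two diagnostic locus sets are also reported: `sire_excluded_loci`, loci
#' where non-maternal alleles exist but none is carried by the putative
#' sire (he cannot be the sole sire there), and `sire_absent_loci`, loci
#' where the pool contains no allele of his at all (with hundreds of
#' pooled embryos this excludes him as a sire outright).
#'
#' @param mass named list of per-locus allele vectors, or a row of a
#'   panel's `masses` table
#' @param mother named list: locus -> mother's allele pair (required)
#' @param putative_sire named list: locus -> partner's allele pair, or
#'   `NULL` when unsampled
#' @param loci loci to consider (default: names of the mother's genotype)
#' @return object of class `pair_classification`: list with `mass_id`,
#'   `call` ("MO"/"EP"/"UNDETERMINED"), `evidence_loci`,
#'   `sire_excluded_loci`, `sire_absent_loci`, and `evidence_alleles`
#'   (named list of the novel alleles per evidence locus)
#' @export
classify_pair <- function(mass, mother, putative_sire = NULL, loci = NULL) {
  if (!is.null(mass$alleles) && is.list(mass$alleles) &&
      !is.null(mass$mass_id)) {
    sets <- if (is.data.frame(mass)) mass$alleles[[1L]] else mass$alleles
    mass_id <- as.character(mass$mass_id)
  } else {
    sets <- mass
    mass_id <- NA_character_
  }
  stopifnot(!is.null(mother))
  if (is.null(loci)) loci <- names(mother)
  if (is.null(putative_sire))
    return(structure(list(mass_id = mass_id, call = "UNDETERMINED",
                          evidence_loci = character(),
                          sire_excluded_loci = character(),
                          sire_absent_loci = character(),
                          evidence_alleles = list()),
                     class = "pair_classification"))
  evidence <- character(); excluded <- character(); absent <- character()
  ev_alleles <- list()
  for (loc in loci) {
    set <- sets[[loc]]
    mg <- mother[[loc]]; sg <- putative_sire[[loc]]
    if (is.null(set)) next
    pair_union <- c(mg, sg)
    novel <- setdiff(set, pair_union)
    if (length(novel)) {
      evidence <- c(evidence, loc)
      ev_alleles[[loc]] <- novel
    }
    if (!is.null(mg)) {
      nonmat <- setdiff(set, mg)
      if (length(nonmat) && !is.null(sg) && !any(nonmat %in% sg))
        excluded <- c(excluded, loc)
    }
    if (!is.null(sg) && !any(set %in% sg)) absent <- c(absent, loc)
  }
  structure(list(mass_id = mass_id,
                 call = if (length(evidence)) "EP" else "MO",
                 evidence_loci = evidence,
                 sire_excluded_loci = excluded,
                 sire_absent_loci = absent,
                 evidence_alleles = ev_alleles),
            class = "pair_classification")
}

#' @export
print.pair_classification <- function(x, ...) {
  cat("<pair_classification> mass ", x$mass_id, ": ", x$call, "\n", sep = "")
  if (length(x$evidence_loci))
    cat("  extra-pair alleles at: ",
        paste(vapply(x$evidence_loci, function(l)
          paste0(l, " (", paste(x$evidence_alleles[[l]], collapse = ","), ")"),
          character(1)), collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Classify all paired masses with a genotyped mother and putative sire
#'
#' @param panel an `msat_panel`
#' @return list with counts `n_EP`, `n_MO`, `n_undetermined` and a
#'   `calls` data.frame (`mass_id`, `call`, `evidence_loci`); masses with
#'   no putative sire recorded are skipped entirely.
#' @export
pair_summary <- function(panel) {
  m <- panel$masses
  keep <- which(!is.na(m$putative_sire_id))
  rows <- lapply(keep, function(i) {
    mother <- .mother_genotypes(panel, m$maternal_id[i])
    if (is.null(mother)) return(NULL)  # mother unsampled: cannot classify
    sire <- .mother_genotypes(panel, m$putative_sire_id[i])
    cl <- classify_pair(m[i, ], mother, sire, loci = panel_loci(panel))
    data.frame(mass_id = cl$mass_id, call = cl$call,
               evidence_loci = paste(cl$evidence_loci, collapse = ";"),
               sire_absent_loci = paste(cl$sire_absent_loci, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mass_id = character(), call = character(),
               evidence_loci = character(), sire_absent_loci = character(),
               stringsAsFactors = FALSE)
  list(n_EP = sum(calls$call == "EP"),
       n_MO = sum(calls$call == "MO"),
       n_undetermined = sum(calls$call == "UNDETERMINED"),
       calls = calls)
}
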