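# Sentinel used in CSV files for a locus with no data and for an adult that
# was never sampled. Internally NO_DATA is NULL in the allele list-column and
# NOT_SAMPLED is NA_character_ in maternal_id / putative_sire_id.
.ND <- "ND"
.NS <- "NS"

#' Construct a microsatellite panel
#'
#' A panel bundles the locus table, the adult multilocus genotypes, and the
#' egg-mass pooled allele sets into one validated object. Alleles are
#' categorical integer labels (PCR fragment lengths in base pairs); no
#' arithmetic is ever performed on them.
#'
#' @param loci data.frame with columns `locus`, `repeat_motif`. A
#'   `motif_length` column is derived.
#' @param adults data.frame with columns `adult_id`, `social_status`,
#'   `shell_length_mm`, then per-locus pair columns `<locus>_a`, `<locus>_b`
#'   (NA = not genotyped at that locus).
#' @param masses data.frame with columns `mass_id`, `maternal_id`,
#'   `maternal_status`, `putative_sire_id` and a list-column `alleles`
#'   (per mass, a named list mapping locus to an integer allele vector, with
#'   `NULL` meaning no data).
#' @return An object of class `msat_panel`.
#' @export
msat_panel <- function(loci, adults, masses) {
  stopifnot(is.data.frame(loci), is.data.frame(adults), is.data.frame(masses))
  loci$locus <- as.character(loci$locus)
  loci$repeat_motif <- toupper(as.character(loci$repeat_motif))
  loci$motif_length <- nchar(loci$repeat_motif)
  if (anyDuplicated(loci$locus))
    stop("duplicate locus name: ", loci$locus[duplicated(loci$locus)][1L])
  if (!all(loci$motif_length %in% 2:4))
    stop("repeat motifs must be di-, tri- or tetranucleotide")
  if (anyDuplicated(adults$adult_id))
    stop("duplicate adult_id: ", adults$adult_id[duplicated(adults$adult_id)][1L])
  ok_status <- c("paired", "solitary", "grouped", "unknown")
  adults$social_status <- as.character(adults$social_status)
  if (!all(adults$social_status %in% ok_status))
    stop("social_status must be one of: ", paste(ok_status, collapse = ", "))
  # normalize allele ordering so allele_a <= allele_b within each call
  for (loc in loci$locus) {
    ca <- paste0(loc, "_a"); cb <- paste0(loc, "_b")
    if (!all(c(ca, cb) %in% names(adults)))
      stop("adults table lacks genotype columns for locus ", loc)
    a <- adults[[ca]]; b <- adults[[cb]]
    if (any(xor(is.na(a), is.na(b))))
      stop("half-missing genotype at locus ", loc, " (one allele NA)")
    if (any(!is.na(a) & (a <= 0 | b <= 0)))
      stop("alleles must be positive integers at locus ", loc)
    swap <- !is.na(a) & a > b
    adults[[ca]] <- ifelse(swap, b, a)
    adults[[cb]] <- ifelse(swap, a, b)
  }
  if (nrow(masses) > 0) {
    stopifnot(is.list(masses$alleles))
    masses$mass_id <- as.character(masses$mass_id)
    if (anyDuplicated(masses$mass_id))
      stop("duplicate mass_id: ", masses$mass_id[duplicated(masses$mass_id)][1L])
    bad_loc <- setdiff(unlist(lapply(masses$alleles, names)), loci$locus)
    if (length(bad_loc))
      stop("egg-mass allele set references unknown locus: ", bad_loc[1L])
    for (i in seq_len(nrow(masses))) {
      sets <- masses$alleles[[i]]
      for (loc in names(sets)) {
        s <- sets[[loc]]
        if (!is.null(s)) {
          if (length(s) < 1L || any(s <= 0) || any(s != as.integer(s)))
            stop("invalid allele set for mass ", masses$mass_id[i],
                 " locus ", loc)
          masses$alleles[[i]][[loc]] <- sort(unique(as.integer(s)))
        }
      }
    }
    resolved <- is.na(masses$maternal_id) |
      masses$maternal_id %in% adults$adult_id
    if (!all(resolved))
      stop("maternal_id does not resolve to an adult (use NS if unsampled): ",
           masses$maternal_id[!resolved][1L])
  }
  structure(list(loci = loci, adults = adults, masses = masses),
            class = "msat_panel")
}

#' @export
print.msat_panel <- function(x, ...) {
  cat("<msat_panel> ", nrow(x$loci), " loci, ", nrow(x$adults), " adults, ",
      nrow(x$masses), " egg masses\n", sep = "")
  cat("  loci: ", paste(x$loci$locus, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Loci of a panel
#' @param panel an `msat_panel`
#' @return character vector of locus names
#' @export
panel_loci <- function(panel) panel$loci$locus

#' Look up one adult's genotype at one locus
#'
#' @param panel an `msat_panel`
#' @param adult_id adult identifier, or NA
#' @param locus locus name
#' @return Integer vector of the two alleles (sorted), or `NULL` if the
#'   adult is unknown/unsampled or not genotyped at the locus.
#' @export
adult_genotype <- function(panel, adult_id, locus) {
  if (is.null(adult_id) || length(adult_id) != 1L || is.na(adult_id))
    return(NULL)
  i <- match(adult_id, panel$adults$adult_id)
  if (is.na(i)) return(NULL)
  g <- c(panel$adults[[paste0(locus, "_a")]][i],
         panel$adults[[paste0(locus, "_b")]][i])
  if (anyNA(g)) NULL else as.integer(g)
}

#' Pooled allele set of one egg mass at one locus
#' @inheritParams adult_genotype
#' @param mass_id egg-mass identifier
#' @return Sorted integer allele vector, or `NULL` for no data.
#' @export
mass_alleles <- function(panel, mass_id, locus) {
  i <- match(as.character(mass_id), panel$masses$mass_id)
  if (is.na(i)) stop("unknown mass_id: ", mass_id)
  panel$masses$alleles[[i]][[locus]]
}

.parse_allele_set <- function(cell, mass_id, locus) {
  cell <- trimws(cell)
  if (is.na(cell) || cell == "" || toupper(cell) == .ND) return(NULL)
  parts <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
  vals <- suppressWarnings(as.numeric(parts))
  if (anyNA(vals) || any(vals != floor(vals)) || any(vals <= 0))
    stop("mass ", mass_id, ", locus ", locus,
         ": allele set must be semicolon-separated positive integers, got '",
         cell, "'")
  sort(unique(as.integer(vals)))
}

#' Read a panel from its three CSV tables
#'
#' Schemas: `loci.csv` has columns `locus,repeat_motif`; `adults.csv` has
#' `adult_id,social_status,shell_length_mm` then `<locus>_a,<locus>_b` pairs
#' (blank = not genotyped); `masses.csv` has
#' `mass_id,maternal_id,maternal_status,putative_sire_id` then one `<locus>`
#' column per locus holding semicolon-separated allele integers, or `ND` for
#' no data. The literal `NS` in `maternal_id`/`putative_sire_id` marks an
#' individual that was never sampled and is mapped to NA.
#'
#' @param adult_table_path,mass_table_path,locus_table_path file paths
#' @return validated `msat_panel`
#' @examples
#' d <- system.file("extdata", "sgigas", package = "poolpat")
#' p <- read_panel(file.path(d, "adults.csv"), file.path(d, "masses.csv"),
#'                 file.path(d, "loci.csv"))
#' p
#' @export
read_panel <- function(adult_table_path, mass_table_path, locus_table_path) {
  for (f in c(adult_table_path, mass_table_path, locus_table_path))
    if (!file.exists(f)) stop("file not found: ", f)
  loci <- utils::read.csv(locus_table_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("locus", "repeat_motif") %in% names(loci)))
    stop("loci table must have columns locus,repeat_motif")

  adults <- utils::read.csv(adult_table_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  need <- c("adult_id", "social_status", "shell_length_mm")
  if (!all(need %in% names(adults)))
    stop("adults table must have columns ", paste(need, collapse = ","))
  adults$adult_id <- as.character(adults$adult_id)
  for (loc in loci$locus) {
    for (col in paste0(loc, c("_a", "_b"))) {
      v <- adults[[col]]
      if (is.null(v)) stop("adults table lacks column ", col)
      if (is.character(v)) v[trimws(v) == ""] <- NA
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & (is.na(vn) | vn != floor(vn)))
      if (length(bad))
        stop("adults row ", bad[1L], ", column ", col,
             ": non-integer allele '", v[bad[1L]], "'")
      adults[[col]] <- as.integer(vn)
    }
  }
  adults$shell_length_mm <- suppressWarnings(as.numeric(adults$shell_length_mm))

  raw <- utils::read.csv(mass_table_path, check.names = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0) {
    masses <- data.frame(mass_id = character(), maternal_id = character(),
                         maternal_status = character(),
                         putative_sire_id = character(),
                         stringsAsFactors = FALSE)
    masses$alleles <- list()
  } else {
    need <- c("mass_id", "maternal_id", "maternal_status", "putative_sire_id")
    if (!all(need %in% names(raw)))
      stop("masses table must have columns ", paste(need, collapse = ","))
    missing_loc <- setdiff(loci$locus, names(raw))
    if (length(missing_loc))
      stop("masses table lacks column for locus ", missing_loc[1L])
    to_na <- function(x) {
      x <- trimws(x)
      x[x == "" | toupper(x) == .NS] <- NA
      x
    }
    masses <- data.frame(mass_id = raw$mass_id,
                         maternal_id = to_na(raw$maternal_id),
                         maternal_status = raw$maternal_status,
                         putative_sire_id = to_na(raw$putative_sire_id),
                         stringsAsFactors = FALSE)
    masses$alleles <- lapply(seq_len(nrow(raw)), function(i) {
      sets <- lapply(loci$locus, function(loc)
        .parse_allele_set(raw[[loc]][i], raw$mass_id[i], loc))
      names(sets) <- loci$locus
      sets
    })
  }
  msat_panel(loci, adults, masses)
}

#' Write a panel back to the three CSV tables
#'
#' Inverse of [read_panel()]: a read-write-read round trip yields an
#' identical panel.
#'
#' @param panel an `msat_panel`
#' @param adult_table_path,mass_table_path,locus_table_path output paths
#' @return invisibly, the three paths
#' @export
write_panel <- function(panel, adult_table_path, mass_table_path,
                        locus_table_path) {
  utils::write.csv(panel$loci[, c("locus", "repeat_motif")],
                   locus_table_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(panel$adults, adult_table_path, row.names = FALSE,
                   quote = FALSE, na = "")
  m <- panel$masses
  out <- data.frame(mass_id = m$mass_id,
                    maternal_id = ifelse(is.na(m$maternal_id), .NS,
                                         m$maternal_id),
                    maternal_status = m$maternal_status,
                    putative_sire_id = ifelse(is.na(m$putative_sire_id), "",
                                              m$putative_sire_id),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (loc in panel_loci(panel)) {
    out[[loc]] <- vapply(m$alleles, function(sets) {
      s <- sets[[loc]]
      if (is.null(s)) .ND else paste(s, collapse = ";")
    }, character(1))
  }
  utils::write.csv(out, mass_table_path, row.names = FALSE, quote = FALSE)
  invisible(c(adult_table_path, mass_table_path, locus_table_path))
}

#' Check that every egg mass carries a maternal allele at every locus
#'
#' Pooled embryos must each inherit one maternal allele, so an egg mass
#' whose allele set shares nothing with its known mother's genotype at a
#' genotyped locus indicates a scoring or identity error.
#'
#' @param panel an `msat_panel`
#' @return data.frame of violations with columns `mass_id`, `locus`,
#'   `mass_alleles`, `maternal_genotype`; zero rows means fully consistent.
#'   Masses with unsampled mothers and loci with no data are skipped.
#' @export
validate_maternal_consistency <- function(panel) {
  rows <- list()
  for (i in seq_len(nrow(panel$masses))) {
    mid <- panel$masses$mass_id[i]
    mom <- panel$masses$maternal_id[i]
    for (loc in panel_loci(panel)) {
      set <- panel$masses$alleles[[i]][[loc]]
      g <- adult_genotype(panel, mom, loc)
      if (is.null(set) || is.null(g)) next
      if (!any(set %in% g))
        rows[[length(rows) + 1L]] <- data.frame(
          mass_id = mid, locus = loc,
          mass_alleles = paste(set, collapse = ";"),
          maternal_genotype = paste(g, collapse = "/"),
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(mass_id = character(), locus = character(),
               mass_alleles = character(), maternal_genotype = character(),
               stringsAsFactors = FALSE)
}

#' Restrict egg-mass allele sets to alleles seen in the adult sample
#'
#' Pooled-brood genotyping can call artifact peaks; a conservative guard is
#' to score an egg mass only for alleles observed in at least one genotyped
#' adult. Removals are recorded in the `"removed"` attribute of the result.
#' An allele set emptied by the filter becomes no-data, with a warning.
#'
#' @param panel an `msat_panel` with at least one genotyped adult
#' @return filtered `msat_panel`; `attr(, "removed")` is a data.frame of
#'   `mass_id`, `locus`, `allele` rows that were dropped.
#' @export
filter_alleles_to_adult_panel <- function(panel) {
  if (nrow(panel$adults) == 0)
    stop("panel has no adults; cannot derive the reference allele set")
  removed <- list()
  for (loc in panel_loci(panel)) {
    seen <- unique(stats::na.omit(c(panel$adults[[paste0(loc, "_a")]],
                                    panel$adults[[paste0(loc, "_b")]])))
    for (i in seq_len(nrow(panel$masses))) {
      set <- panel$masses$alleles[[i]][[loc]]
      if (is.null(set)) next
      drop <- setdiff(set, seen)
      if (length(drop)) {
        removed[[length(removed) + 1L]] <- data.frame(
          mass_id = panel$masses$mass_id[i], locus = loc, allele = drop,
          stringsAsFactors = FALSE)
        keep <- intersect(set, seen)
        if (length(keep) == 0L) {
          warning("mass ", panel$masses$mass_id[i], ", locus ", loc,
                  ": all alleles removed by adult-panel filter; set to ND")
          panel$masses$alleles[[i]][loc] <- list(NULL)
        } else {
          panel$masses$alleles[[i]][[loc]] <- keep
        }
      }
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(mass_id = character(), locus = character(),
               allele = integer(), stringsAsFactors = FALSE)
  attr(panel, "removed") <- removed
  panel
}

#' Load the bundled limpet microsatellite dataset
#'
#' Sixteen egg masses and sixteen adults of the intertidal limpet
#' *Siphonaria gigas* genotyped at four microsatellite loci; see the
#' provenance README in `inst/extdata/sgigas/`.
#'
#' @return an `msat_panel`
#' @export
sgigas_panel <- function() {
  d <- system.file("extdata", "sgigas", package = "poolpat")
  if (d == "") stop("bundled fixture not found")
  read_panel(file.path(d, "adults.csv"), file.path(d, "masses.csv"),
             file.path(d, "loci.csv"))
}
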