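# Shared builders for small in-code fixtures.

# adults data.frame for a single locus named "L" from a list of allele pairs
# (NULL = not genotyped)
adults_one_locus <- function(pairs, status = "unknown") {
  n <- length(pairs)
  df <- data.frame(adult_id = sprintf("A%03d", seq_len(n)),
                   social_status = status, shell_length_mm = NA_real_,
                   stringsAsFactors = FALSE)
  df$L_a <- vapply(pairs, function(g) if (is.null(g)) NA_integer_ else
    as.integer(min(g)), integer(1))
  df$L_b <- vapply(pairs, function(g) if (is.null(g)) NA_integer_ else
    as.integer(max(g)), integer(1))
  df
}

# a tiny two-locus panel with two adults and one egg mass, built in code
toy_panel <- function(mass_sets = list(LA = c(100, 102), LB = c(200)),
                      maternal_id = "A001", putative_sire_id = NA) {
  loci <- data.frame(locus = c("LA", "LB"), repeat_motif = c("AC", "TAA"),
                     stringsAsFactors = FALSE)
  adults <- data.frame(
    adult_id = c("A001", "A002"),
    social_status = c("paired", "paired"),
    shell_length_mm = c(50, 48),
    LA_a = c(100L, 102L), LA_b = c(102L, 104L),
    LB_a = c(200L, 203L), LB_b = c(200L, 206L),
    stringsAsFactors = FALSE)
  masses <- data.frame(mass_id = "m1", maternal_id = maternal_id,
                       maternal_status = "paired",
                       putative_sire_id = putative_sire_id,
                       stringsAsFactors = FALSE)
  masses$alleles <- list(mass_sets)
  msat_panel(loci, adults, masses)
}

# random frequency vector with k alleles (strictly positive entries)
random_freqs <- function(k) {
  x <- rgamma(k, shape = 1) + 1e-3
  x / sum(x)
}

sgigas_fixture_dir <- function() {
  system.file("extdata", "sgigas", package = "poolpat")
}
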