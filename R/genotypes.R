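#' Construct and validate a genotype matrix
#'
#' Genotypes are stored as an integer matrix of counted-allele dosages with
#' samples in rows and variants in columns. Entries are 0, 1 or 2 copies of
#' the counted allele; missing calls are `NA` (never a numeric sentinel such
#' as -9). Row names are sample identifiers, column names variant identifiers.
#'
#' @param calls numeric/integer matrix of dosages in \{0, 1, 2, NA\}.
#' @param sample_ids,variant_ids identifier vectors; default to existing
#'   dimnames or generated `S1..`/`V1..` labels.
#' @return validated integer matrix with dimnames set.
#' @export
genotype_matrix <- function(calls, sample_ids = NULL, variant_ids = NULL) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  sample_ids <- sample_ids %||% rownames(calls) %||%
    paste0("S", seq_len(nrow(calls)))
  variant_ids <- variant_ids %||% colnames(calls) %||%
    paste0("V", seq_len(ncol(calls)))
  if (length(sample_ids) != nrow(calls)) {
    stopf("sample_ids length (%d) != number of rows (%d)",
          length(sample_ids), nrow(calls))
  }
  if (length(variant_ids) != ncol(calls)) {
    stopf("variant_ids length (%d) != number of columns (%d)",
          length(variant_ids), ncol(calls))
  }
  dimnames(calls) <- list(as.character(sample_ids), as.character(variant_ids))
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stopf("%d genotype calls outside {0,1,2,NA}", sum(bad))
  calls
}

validate_genotypes <- function(g) {
  stopifnot(is.matrix(g))
  if (any(!(g %in% c(0L, 1L, 2L, NA)))) {
    stopf("genotype matrix contains values outside {0,1,2,NA}")
  }
  invisible(g)
}

#' Per-sample and per-variant metadata tables
#'
#' `sample_table()` records, per individual, the breed/population label, an
#' optional continental/status group (e.g. "Asian-Domestic"), sampling
#' coordinates in decimal degrees, and the genotyping call rate.
#' `variant_table()` records, per SNP, chromosome, 1-based physical position,
#' the two alleles (the counted allele is `alt`), and an optional cumulative
#' genetic-map position in Morgans.
#'
#' @param sample_id,population character vectors (population must be non-empty).
#' @param group optional group label per sample.
#' @param lat,lon optional decimal degrees; validated to \[-90,90\]/\[-180,180\].
#' @param call_rate optional fraction in \[0,1\].
#' @return data.frame with one row per sample.
#' @export
sample_table <- function(sample_id, population, group = NA_character_,
                         lat = NA_real_, lon = NA_real_,
                         call_rate = NA_real_) {
  n <- length(sample_id)
  meta <- data.frame(
    sample_id = as.character(sample_id),
    population = as.character(population),
    group = rep_len(as.character(group), n),
    lat = rep_len(as.numeric(lat), n),
    lon = rep_len(as.numeric(lon), n),
    call_rate = rep_len(as.numeric(call_rate), n),
    stringsAsFactors = FALSE
  )
  if (any(is.na(meta$population) | meta$population == "")) {
    stopf("population labels must be non-empty")
  }
  ok_lat <- is.na(meta$lat) | (meta$lat >= -90 & meta$lat <= 90)
  ok_lon <- is.na(meta$lon) | (meta$lon >= -180 & meta$lon <= 180)
  if (!all(ok_lat)) stopf("latitude outside [-90, 90]")
  if (!all(ok_lon)) stopf("longitude outside [-180, 180]")
  meta
}

#' @rdname sample_table
#' @param variant_id,chrom,pos per-variant identifier, chromosome, 1-based bp.
#' @param ref,alt allele labels; `alt` is the counted allele.
#' @param genetic_pos cumulative genetic-map position in Morgans (optional).
#' @export
variant_table <- function(variant_id, chrom, pos, ref = "A", alt = "B",
                          genetic_pos = NA_real_) {
  n <- length(variant_id)
  vars <- data.frame(
    variant_id = as.character(variant_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    genetic_pos = rep_len(as.numeric(genetic_pos), n),
    stringsAsFactors = FALSE
  )
  for (ch in unique(vars$chrom)) {
    p <- vars$pos[vars$chrom == ch]
    sp <- sort(p)
    if (anyDuplicated(sp)) stopf("duplicated position on chromosome %s", ch)
    gp <- vars$genetic_pos[vars$chrom == ch][order(p)]
    if (!all(is.na(gp)) && is.unsorted(gp, na.rm = TRUE)) {
      stopf("genetic positions not non-decreasing on chromosome %s", ch)
    }
  }
  vars
}

#' Allele frequencies, MAF and call rates
#'
#' Frequencies of the counted allele are computed over called genotypes only.
#'
#' @param g genotype matrix (see [genotype_matrix()]).
#' @return numeric vector, one value per variant (or per sample for
#'   `sample_call_rate()`).
#' @export
allele_freq <- function(g) {
  colMeans(g, na.rm = TRUE) / 2
}

#' @rdname allele_freq
#' @export
maf <- function(g) {
  p <- allele_freq(g)
  pmin(p, 1 - p)
}

#' @rdname allele_freq
#' @export
variant_call_rate <- function(g) {
  colMeans(!is.na(g))
}

#' @rdname allele_freq
#' @export
sample_call_rate <- function(g) {
  rowMeans(!is.na(g))
}

#' Swap the counted allele at selected variants
#'
#' Maps dosage d to 2 - d at the given variant columns, leaving missing calls
#' missing. MAF is invariant under this flip.
#'
#' @param g genotype matrix.
#' @param variants index vector of columns to flip (default all).
#' @return flipped genotype matrix.
#' @export
flip_alleles <- function(g, variants = seq_len(ncol(g))) {
  g[, variants] <- 2L - g[, variants, drop = FALSE]
  g
}
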