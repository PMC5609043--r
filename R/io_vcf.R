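# VCF 4.x genotype I/O. Reading goes through vcfR; the counted allele is the
# ALT allele, so dosage is the ALT-allele count of the GT field. Writing emits
# plain-text VCF with "./." for missing calls.

read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  m <- nrow(fix)
  ids <- fix$ID
  if (is.null(ids) || any(is.na(ids) | ids == ".")) {
    auto <- paste0(fix$CHROM, "_", fix$POS)
    ids <- ifelse(is.na(ids) | ids == ".", auto, ids)
  }
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    stopf("multi-allelic records not supported (%d found, first: %s)",
          sum(multi), ids[which(multi)[1]])
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0 && m > 0) {
    stopf("VCF has no GT genotype field")
  }
  # gt: variants x samples, entries like 0/0, 0|1, ./.
  count_alt <- function(x) {
    al <- strsplit(x, "[/|]")
    vapply(al, function(a) {
      if (any(a == "." | is.na(a))) return(NA_integer_)
      sum(a == "1")
    }, integer(1))
  }
  gt[is.na(gt)] <- "./."
  calls <- t(apply(gt, 2, function(col) count_alt(col)))
  calls <- matrix(as.integer(calls), ncol(gt), m)
  g <- genotype_matrix(calls, colnames(gt), ids)
  meta <- sample_table(colnames(gt), population = "unknown",
                       call_rate = sample_call_rate(g))
  vars <- variant_table(ids, fix$CHROM, as.integer(fix$POS),
                        ref = fix$REF, alt = fix$ALT)
  list(genotypes = g, samples = meta, variants = vars)
}

write_vcf_genotypes <- function(g, meta, vars, path) {
  stopifnot(nrow(g) == nrow(meta), ncol(g) == nrow(vars))
  gt_of <- function(d) {
    out <- rep("./.", length(d))
    out[!is.na(d) & d == 0L] <- "0/0"
    out[!is.na(d) & d == 1L] <- "0/1"
    out[!is.na(d) & d == 2L] <- "1/1"
    out
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pigpopgen",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", meta$sample_id), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(vars)), function(j) {
    paste(c(vars$chrom[j], vars$pos[j], vars$variant_id[j],
            vars$ref[j], vars$alt[j], ".", "PASS", ".", "GT",
            gt_of(g[, j])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read or write genotypes in PLINK or VCF layout
#'
#' @param path for `format = "vcf"` the VCF file path; for `"ped"`/`"bed"`
#'   the PLINK fileset prefix (without extension).
#' @param format one of `"ped"` (PED/MAP text), `"bed"` (BED/BIM/FAM binary,
#'   variant-major) or `"vcf"`.
#' @return `read_genotypes()`: a list with elements `genotypes` (dosage
#'   matrix, see [genotype_matrix()]), `samples` (see [sample_table()]) and
#'   `variants` (see [variant_table()]). Variant order is file order.
#' @export
read_genotypes <- function(path, format = c("ped", "bed", "vcf")) {
  format <- match.arg(format)
  switch(format,
         ped = read_ped(path),
         bed = read_bed(path),
         vcf = read_vcf_genotypes(path))
}

#' @rdname read_genotypes
#' @param g,meta,vars genotype matrix and matching sample/variant tables.
#' @export
write_genotypes <- function(g, meta, vars, path,
                            format = c("ped", "bed", "vcf")) {
  format <- match.arg(format)
  validate_genotypes(g)
  switch(format,
         ped = write_ped(g, meta, vars, path),
         bed = write_bed(g, meta, vars, path),
         vcf = write_vcf_genotypes(g, meta, vars, path))
  invisible(path)
}
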