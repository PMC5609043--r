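# PLINK text (PED/MAP) and binary (BED/BIM/FAM, v1.9 variant-major) I/O.
#
# Counted-allele convention: the alternate allele of the variant table is
# counted. On PED input, where the file carries no designation, the counted
# allele of a biallelic column is the lexicographically greater allele label
# (this subsumes PLINK's 1/2 recoding, where "2" is counted); a monomorphic
# column is read as dosage 0 of its single observed allele. In BIM files the
# first allele column (A1) is the counted allele, matching the .bed genotype
# codes of PLINK 1.9.

read_ped <- function(prefix) {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  for (p in c(ped_path, map_path)) {
    if (!file.exists(p)) stopf("file not found: %s", p)
  }
  map <- if (length(grep("[^[:space:]]", readLines(map_path))) == 0) {
    data.frame(chrom = character(), variant_id = character(),
               genetic_pos = numeric(), pos = integer(),
               stringsAsFactors = FALSE)
  } else {
    m0 <- utils::read.table(map_path, header = FALSE,
                            colClasses = c("character", "character",
                                           "numeric", "integer"))
    names(m0) <- c("chrom", "variant_id", "genetic_pos", "pos")
    m0
  }
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  calls <- matrix(NA_integer_, n, m)
  fid <- character(n); iid <- character(n)
  a_first <- matrix(NA_character_, n, m)
  a_second <- matrix(NA_character_, n, m)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * m) {
      stopf("PED parse error at line %d: expected %d fields, found %d",
            i, 6 + 2 * m, length(tok))
    }
    fid[i] <- tok[1]; iid[i] <- tok[2]
    if (m > 0) {
      al <- tok[-(1:6)]
      a_first[i, ] <- al[seq(1, 2 * m, by = 2)]
      a_second[i, ] <- al[seq(2, 2 * m, by = 2)]
    }
  }
  ref <- character(m); alt <- character(m)
  for (j in seq_len(m)) {
    a1 <- a_first[, j]; a2 <- a_second[, j]
    miss <- a1 == "0" | a2 == "0"
    alleles <- sort(unique(c(a1[!miss], a2[!miss])))
    if (length(alleles) > 2) {
      stopf("variant %s has %d alleles; only biallelic sites supported",
            map$variant_id[j], length(alleles))
    }
    if (length(alleles) == 0) alleles <- c("0", "0")
    if (length(alleles) == 1) alleles <- c(alleles, alleles)
    ref[j] <- alleles[1]; alt[j] <- alleles[2]
    d <- (a1 == alt[j]) + (a2 == alt[j])
    d[miss] <- NA_integer_
    calls[, j] <- as.integer(d)
  }
  g <- genotype_matrix(calls, iid, map$variant_id)
  meta <- sample_table(iid, population = fid,
                       call_rate = sample_call_rate(g))
  vars <- variant_table(map$variant_id, map$chrom, map$pos, ref, alt,
                        genetic_pos = map$genetic_pos)
  list(genotypes = g, samples = meta, variants = vars)
}

write_ped <- function(g, meta, vars, prefix) {
  stopifnot(nrow(g) == nrow(meta), ncol(g) == nrow(vars))
  map <- data.frame(vars$chrom, vars$variant_id,
                    ifelse(is.na(vars$genetic_pos), 0, vars$genetic_pos),
                    vars$pos)
  utils::write.table(map, paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  m <- ncol(g)
  lines <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    d <- g[i, ]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, vars$alt, vars$ref))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2, vars$alt, vars$ref))
    pair <- character(2 * m)
    if (m > 0) {
      pair[seq(1, 2 * m, 2)] <- a1
      pair[seq(2, 2 * m, 2)] <- a2
    }
    lines[i] <- paste(c(meta$population[i], meta$sample_id[i],
                        "0", "0", "0", "-9", pair), collapse = " ")
  }
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

# .bed genotype codes (2 bits, variant-major): 00 = hom counted (dosage 2),
# 10 = het, 11 = hom other (dosage 0), 01 = missing.
read_bed <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stopf("file not found: %s", p)
  }
  bim <- utils::read.table(bim_path, header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "variant_id", "genetic_pos", "pos", "a1", "a2")
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stopf("%s is not a PLINK .bed file (bad magic)", bed_path)
  }
  if (raw[3] != as.raw(0x01)) {
    stopf("only variant-major (SNP-major) .bed supported")
  }
  bpv <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bpv * m) {
    stopf(".bed size mismatch: expected %d data bytes, found %d",
          bpv * m, length(body))
  }
  # decode 2-bit codes; lookup by code value
  dosage_of <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  ints <- as.integer(body)
  codes <- matrix(NA_integer_, 4 * bpv, m)
  bm <- matrix(ints, bpv, m)
  codes[seq(1, 4 * bpv, 4), ] <- bm %% 4L
  codes[seq(2, 4 * bpv, 4), ] <- (bm %/% 4L) %% 4L
  codes[seq(3, 4 * bpv, 4), ] <- (bm %/% 16L) %% 4L
  codes[seq(4, 4 * bpv, 4), ] <- (bm %/% 64L) %% 4L
  calls <- matrix(dosage_of[as.character(codes[seq_len(n), , drop = FALSE])],
                  n, m)
  g <- genotype_matrix(calls, fam[[2]], bim$variant_id)
  meta <- sample_table(fam[[2]], population = fam[[1]],
                       call_rate = sample_call_rate(g))
  vars <- variant_table(bim$variant_id, bim$chrom, bim$pos,
                        ref = bim$a2, alt = bim$a1,
                        genetic_pos = bim$genetic_pos)
  list(genotypes = g, samples = meta, variants = vars)
}

write_bed <- function(g, meta, vars, prefix) {
  stopifnot(nrow(g) == nrow(meta), ncol(g) == nrow(vars))
  bim <- data.frame(vars$chrom, vars$variant_id,
                    ifelse(is.na(vars$genetic_pos), 0, vars$genetic_pos),
                    vars$pos, vars$alt, vars$ref)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  fam <- data.frame(meta$population, meta$sample_id, "0", "0", "0", "-9")
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  n <- nrow(g); m <- ncol(g)
  code_of <- function(d) {
    out <- integer(length(d))
    out[is.na(d)] <- 1L
    out[!is.na(d) & d == 2L] <- 0L
    out[!is.na(d) & d == 1L] <- 2L
    out[!is.na(d) & d == 0L] <- 3L
    out
  }
  bpv <- ceiling(n / 4)
  padded <- 4L * bpv
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  out <- raw(bpv * m)
  for (j in seq_len(m)) {
    cd <- integer(padded)          # pad with 0b00 per PLINK spec
    cd[seq_len(n)] <- code_of(g[, j])
    b <- cd[seq(1, padded, 4)] + 4L * cd[seq(2, padded, 4)] +
      16L * cd[seq(3, padded, 4)] + 64L * cd[seq(4, padded, 4)]
    out[((j - 1L) * bpv + 1L):(j * bpv)] <- as.raw(b)
  }
  writeBin(out, con)
  invisible(prefix)
}
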