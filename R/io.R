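#' Read genotypes from a HapMap-style tab-delimited file
#'
#' Expects a header row starting `rs# alleles chrom pos strand ...` followed
#' by one sample-id column per sample, genotypes written as two-letter
#' strings (e.g. `AA`, `AG`).  `NN` (or any token that is not a pair of the
#' locus's alleles) maps to missing; unexpected tokens raise a warning.
#' Multi-allelic and indel records are skipped with a logged count;
#' duplicated positions are an error.
#'
#' @param path File path.
#' @param populations Optional named character vector mapping sample id to
#'   population label (default: one population `"pop1"`).
#' @param sex Optional named character vector mapping sample id to sex.
#' @return A [genotype_matrix()]; attribute `n_skipped` counts skipped
#'   records.
#' @export
read_hapmap <- function(path, populations = NULL, sex = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  fixed <- c("rs#", "alleles", "chrom", "pos", "strand")
  if (!all(fixed %in% names(tab)[seq_along(fixed)])) {
    abort("not a HapMap-style genotype file: expected header rs#/alleles/chrom/pos/strand")
  }
  meta_cols <- seq_len(which(names(tab) == "strand"))
  sample_ids <- names(tab)[-meta_cols]
  al <- strsplit(tab$alleles, "/", fixed = TRUE)
  ok <- lengths(al) == 2 &
    vapply(al, function(a) all(nchar(a) == 1), logical(1))
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    inform(sprintf("read_hapmap: skipped %d non-biallelic-SNP records", n_skipped))
  }
  tab <- tab[ok, , drop = FALSE]
  al <- al[ok]
  a1 <- vapply(al, `[`, character(1), 1)
  a2 <- vapply(al, `[`, character(1), 2)
  geno <- as.matrix(tab[, sample_ids, drop = FALSE])
  n_loci <- nrow(tab)
  calls <- matrix(CALL_MISSING, nrow = length(sample_ids), ncol = n_loci)
  unknown <- 0L
  for (j in seq_len(n_loci)) {
    g <- geno[j, ]
    hom1 <- paste0(a1[j], a1[j]); hom2 <- paste0(a2[j], a2[j])
    het <- c(paste0(a1[j], a2[j]), paste0(a2[j], a1[j]))
    calls[, j] <- ifelse(g == hom1, CALL_HOMREF,
                  ifelse(g == hom2, CALL_HOMALT,
                  ifelse(g %in% het, CALL_HET, CALL_MISSING)))
    unknown <- unknown + sum(!(g %in% c(hom1, hom2, het, "NN")))
  }
  if (unknown > 0) {
    warn(sprintf("read_hapmap: %d genotype tokens not matching locus alleles set to missing", unknown))
  }
  loci <- tibble(
    id = tab[["rs#"]],
    chromosome = sub("^chr", "", tab$chrom),
    position_bp = as.integer(tab$pos),
    allele_a = a1, allele_b = a2
  )
  ord <- order(loci$chromosome, loci$position_bp)
  loci <- loci[ord, ]
  calls <- calls[, ord, drop = FALSE]
  samples <- tibble(
    id = sample_ids,
    population = if (is.null(populations)) "pop1" else unname(populations[sample_ids]),
    sex = if (is.null(sex)) "unknown" else unname(sex[sample_ids])
  )
  out <- genotype_matrix(calls, loci, samples)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write genotypes in the HapMap-style dialect read by [read_hapmap()]
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hapmap <- function(gm, path) {
  n_loci <- ncol(gm$calls)
  geno <- matrix("NN", nrow = n_loci, ncol = nrow(gm$calls))
  for (j in seq_len(n_loci)) {
    a <- gm$loci$allele_a[j]; b <- gm$loci$allele_b[j]
    codes <- c(paste0(a, a), paste0(a, b), paste0(b, b), "NN")
    geno[j, ] <- codes[gm$calls[, j] + 1L]
  }
  tab <- cbind(
    data.frame(
      `rs#` = gm$loci$id,
      alleles = paste(gm$loci$allele_a, gm$loci$allele_b, sep = "/"),
      chrom = gm$loci$chromosome,
      pos = gm$loci$position_bp,
      strand = "+",
      check.names = FALSE
    ),
    setNames(as.data.frame(geno), gm$samples$id)
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Biallelic SNP records are converted to genotype codes; multi-allelic and
#' indel records are skipped with a logged count.  Two records at the same
#' chromosome and position are an error.
#'
#' @param path Path to a VCF (v4.x) file.
#' @inheritParams read_hapmap
#' @return A [genotype_matrix()]; attribute `n_skipped` counts skipped
#'   records.
#' @export
read_vcf_genotypes <- function(path, populations = NULL, sex = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ok <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !is.na(fix$ALT) & !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    inform(sprintf("read_vcf_genotypes: skipped %d non-biallelic-SNP records", n_skipped))
  }
  gt <- vcfR::extract.gt(v, element = "GT")[ok, , drop = FALSE]
  fix <- fix[ok, , drop = FALSE]
  sample_ids <- colnames(gt)
  code_gt <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(CALL_MISSING, length(g))
    out[g %in% c("0/0")] <- CALL_HOMREF
    out[g %in% c("0/1", "1/0")] <- CALL_HET
    out[g %in% c("1/1")] <- CALL_HOMALT
    out
  }
  calls <- t(apply(gt, 1, code_gt))
  if (nrow(fix) == 1) calls <- matrix(calls, nrow = 1)
  loci <- tibble(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chromosome = sub("^chr", "", fix$CHROM),
    position_bp = as.integer(fix$POS),
    allele_a = fix$REF, allele_b = fix$ALT
  )
  if (anyDuplicated(loci[, c("chromosome", "position_bp")])) {
    abort("duplicate chromosome+position records in VCF")
  }
  ord <- order(loci$chromosome, loci$position_bp)
  samples <- tibble(
    id = sample_ids,
    population = if (is.null(populations)) "pop1" else unname(populations[sample_ids]),
    sex = if (is.null(sex)) "unknown" else unname(sex[sample_ids])
  )
  out <- genotype_matrix(t(calls)[, ord, drop = FALSE], loci[ord, ], samples)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a region mask from a BED file
#'
#' BED's 0-based half-open intervals are converted to the package's 1-based
#' inclusive convention.  The 4th column, when present, is the interval
#' kind (`cnv`, `igv`, `abnormality`); the 5th a CNV frequency.
#'
#' @param path BED file path.
#' @param default_kind Kind used when the file has no name column.
#' @return A [region_mask()].
#' @export
read_bed_mask <- function(path, default_kind = "cnv") {
  bed <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  kind <- if (ncol(bed) >= 4) bed[[4]] else rep(default_kind, nrow(bed))
  freq <- if (ncol(bed) >= 5) suppressWarnings(as.numeric(bed[[5]])) else
    rep(NA_real_, nrow(bed))
  region_mask(
    chromosome = sub("^chr", "", bed[[1]]),
    start_bp = as.integer(bed[[2]]) + 1L,
    end_bp = as.integer(bed[[3]]),
    kind = kind,
    cnv_frequency = freq
  )
}

#' Read a genetic map (position to centimorgan table)
#'
#' @param path Tab-delimited file with columns `chromosome`, `position_bp`,
#'   `cm` (header required).
#' @return A tibble sorted by chromosome and position.
#' @export
read_genetic_map <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(
    chromosome = "c", position_bp = "i", cm = "d"
  ), progress = FALSE)
  arrange(map, .data$chromosome, .data$position_bp)
}

#' Read a chromosome-arm recombination rate table
#'
#' @param path Tab-delimited file with columns `chromosome`, `arm`,
#'   `start_bp`, `end_bp`, `cm_per_mb`.
#' @return A tibble.
#' @export
read_arm_rates <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chromosome = "c", arm = "c", start_bp = "i", end_bp = "i", cm_per_mb = "d"
  ), progress = FALSE)
}

#' Write a segment table as TSV or BED
#'
#' @param segments A segment tibble from [detect_segments()] /
#'   [annotate_segments()].
#' @param path Output path.
#' @param format `"tsv"` (all columns) or `"bed"` (0-based half-open,
#'   sample id in the name field).
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(segments, path, progress = FALSE)
  } else {
    bed <- tibble(
      chrom = segments$chromosome,
      start = segments$start_bp - 1L,
      end = segments$end_bp,
      name = segments$sample_id
    )
    readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}
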