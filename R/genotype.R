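#' Construct a genotype matrix object
#'
#' The central container for diploid SNP calls: an integer matrix of
#' genotype codes (0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, 3 = missing) with per-locus and per-sample
#' metadata.  Loci must be strictly ordered by (chromosome, position) with
#' unique positions per chromosome.
#'
#' @param calls Integer matrix, samples in rows, loci in columns, values in
#'   `{0, 1, 2, 3}`.
#' @param loci Data frame with one row per locus: columns `id`, `chromosome`,
#'   `position_bp` (1-based), `allele_a`, `allele_b`, and optionally `arm`
#'   (`"p"` or `"q"`, used for genetic-length conversion).
#' @param samples Data frame with one row per sample: columns `id`,
#'   `population`, and optionally `sex` (`"male"`, `"female"`, `"unknown"`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, loci, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  loci <- as_tibble(loci)
  samples <- as_tibble(samples)
  if (!"arm" %in% names(loci)) loci$arm <- "p"
  if (!"sex" %in% names(samples)) samples$sex <- "unknown"
  gm <- structure(
    list(calls = calls, loci = loci, samples = samples),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(gm)
}

validate_genotype_matrix <- function(gm) {
  calls <- gm$calls
  loci <- gm$loci
  samples <- gm$samples
  if (nrow(calls) != nrow(samples)) {
    abort("`calls` rows must match `samples` rows")
  }
  if (ncol(calls) != nrow(loci)) {
    abort("`calls` columns must match `loci` rows")
  }
  if (nrow(loci) > 0) {
    bad <- !calls %in% c(0L, 1L, 2L, 3L)
    if (any(bad)) abort("genotype calls must be in {0, 1, 2, 3}")
    if (any(loci$position_bp < 1)) abort("locus positions must be >= 1")
    ord <- order(loci$chromosome, loci$position_bp)
    if (!identical(ord, seq_len(nrow(loci)))) {
      abort("loci must be sorted by (chromosome, position_bp)")
    }
    dup <- duplicated(loci[, c("chromosome", "position_bp")])
    if (any(dup)) {
      abort(sprintf(
        "duplicate locus position: %s:%d",
        loci$chromosome[dup][1], loci$position_bp[dup][1]
      ))
    }
  }
  if (anyDuplicated(samples$id)) abort("sample ids must be unique")
  dimnames(gm$calls) <- list(samples$id, loci$id)
  gm
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d loci (%d chromosome%s, %d population%s)\n",
    nrow(x$calls), ncol(x$calls),
    length(unique(x$loci$chromosome)),
    if (length(unique(x$loci$chromosome)) == 1) "" else "s",
    length(unique(x$samples$population)),
    if (length(unique(x$samples$population)) == 1) "" else "s"
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Tidy a genotype matrix into long form
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per (sample, locus) call.
#' @export
tidy.genotype_matrix <- function(x, ...) {
  tibble(
    sample_id = rep(x$samples$id, times = ncol(x$calls)),
    population = rep(x$samples$population, times = ncol(x$calls)),
    locus_id = rep(x$loci$id, each = nrow(x$calls)),
    chromosome = rep(x$loci$chromosome, each = nrow(x$calls)),
    position_bp = rep(x$loci$position_bp, each = nrow(x$calls)),
    call = as.integer(x$calls)
  )
}

#' @export
glance.genotype_matrix <- function(x, ...) {
  tibble(
    n_samples = nrow(x$calls),
    n_loci = ncol(x$calls),
    n_chromosomes = length(unique(x$loci$chromosome)),
    n_populations = length(unique(x$samples$population)),
    missing_rate = mean(x$calls == CALL_MISSING),
    het_rate = mean(x$calls == CALL_HET)
  )
}

#' Subset a genotype matrix by loci and/or samples
#'
#' @param gm A [genotype_matrix()].
#' @param loci Integer or logical index over loci (optional).
#' @param samples Integer or logical index over samples (optional).
#' @return A [genotype_matrix()].
#' @export
subset_genotypes <- function(gm, loci = NULL, samples = NULL) {
  if (is.null(loci)) loci <- seq_len(ncol(gm$calls))
  if (is.null(samples)) samples <- seq_len(nrow(gm$calls))
  genotype_matrix(
    gm$calls[samples, loci, drop = FALSE],
    gm$loci[loci, , drop = FALSE],
    gm$samples[samples, , drop = FALSE]
  )
}

locus_call_counts <- function(gm) {
  calls <- gm$calls
  tibble(
    locus_id = gm$loci$id,
    n_homref = unname(colSums(calls == CALL_HOMREF)),
    n_het = unname(colSums(calls == CALL_HET)),
    n_homalt = unname(colSums(calls == CALL_HOMALT)),
    n_missing = unname(colSums(calls == CALL_MISSING))
  )
}

#' Per-locus minor allele frequency
#'
#' MAF is computed from non-missing calls as
#' `(2 * hom_minor + het) / (2 * n_called)`.
#'
#' @param gm A [genotype_matrix()].
#' @return A tibble with columns `locus_id`, `n_called`, `maf`
#'   (`NA` for loci with no calls).
#' @export
locus_maf <- function(gm) {
  cc <- locus_call_counts(gm)
  n_called <- cc$n_homref + cc$n_het + cc$n_homalt
  alt <- 2 * cc$n_homalt + cc$n_het
  af <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  tibble(
    locus_id = cc$locus_id,
    n_called = n_called,
    maf = pmin(af, 1 - af)
  )
}

#' Remove loci with low minor allele frequency
#'
#' Loci with pooled MAF less than or equal to `min_maf` are removed, as are
#' loci with zero non-missing calls (counted in the `n_dropped_nocall`
#' attribute).  Applying the filter twice equals applying it once.
#'
#' @param gm A [genotype_matrix()].
#' @param min_maf Threshold in `[0, 0.5]`; loci are kept when MAF is
#'   strictly greater than this value.
#' @return A filtered [genotype_matrix()].
#' @export
filter_maf <- function(gm, min_maf = 0.05) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  m <- locus_maf(gm)
  nocall <- m$n_called == 0
  keep <- !nocall & m$maf > min_maf
  if (any(nocall)) {
    inform(sprintf("filter_maf: removed %d loci with no non-missing calls", sum(nocall)))
  }
  out <- subset_genotypes(gm, loci = keep)
  attr(out, "n_dropped_maf") <- sum(!keep & !nocall)
  attr(out, "n_dropped_nocall") <- sum(nocall)
  out
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on one locus's genotype counts, conditioning on the
#' observed allele counts: the p-value is the sum of the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed count (the Wigginton-Cutler-Abecasis formulation).
#'
#' @param n_homref,n_het,n_homalt Non-negative genotype counts; their sum
#'   must be at least 1.
#' @return The exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_homref, n_het, n_homalt) {
  stopifnot(n_homref >= 0, n_het >= 0, n_homalt >= 0)
  n <- n_homref + n_het + n_homalt
  if (n < 1) abort("all genotype counts are zero")
  # rare allele count; conditional distribution is over het counts of the
  # same parity as n_rare
  n_rare <- 2 * min(n_homref, n_homalt) + n_het
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # unnormalised log-probabilities of each possible het count
  log_p <- vapply(hets, function(h) {
    rare_hom <- (n_rare - h) / 2
    common_hom <- n - h - rare_hom
    h * log(2) - lfactorial(rare_hom) - lfactorial(h) - lfactorial(common_hom)
  }, numeric(1))
  p <- exp(log_p - max(log_p))
  p <- p / sum(p)
  p_obs <- p[hets == n_het]
  min(1, sum(p[p <= p_obs + 1e-12]))
}

#' Filter loci by the HWE exact test
#'
#' Removes loci whose pooled-genotype HWE exact p-value falls below a
#' removal threshold.  The threshold is configuration, not a fixed rule.
#'
#' @param gm A [genotype_matrix()].
#' @param p_threshold Loci with p-value `<` this are removed.
#' @return A filtered [genotype_matrix()].
#' @export
filter_hwe <- function(gm, p_threshold = 1e-6) {
  cc <- locus_call_counts(gm)
  p <- vapply(seq_len(nrow(cc)), function(i) {
    if (cc$n_homref[i] + cc$n_het[i] + cc$n_homalt[i] == 0) return(NA_real_)
    hwe_exact_test(cc$n_homref[i], cc$n_het[i], cc$n_homalt[i])
  }, numeric(1))
  keep <- is.na(p) | p >= p_threshold
  subset_genotypes(gm, loci = keep)
}

#' Construct a region mask
#'
#' Intervals flagged as copy-number variable (`cnv`), immunoglobulin
#' variable region (`igv`), or gross chromosomal abnormality
#' (`abnormality`).  Coordinates are 1-based inclusive.
#'
#' @param chromosome,start_bp,end_bp Interval coordinates.
#' @param kind One of `"cnv"`, `"igv"`, `"abnormality"` per interval.
#' @param cnv_frequency Population frequency in `[0, 1]` per CNV interval
#'   (`NA` for other kinds).
#' @return A tibble of class `region_mask`.
#' @export
region_mask <- function(chromosome = character(), start_bp = integer(),
                        end_bp = integer(), kind = character(),
                        cnv_frequency = rep(NA_real_, length(chromosome))) {
  stopifnot(all(kind %in% c("cnv", "igv", "abnormality")))
  if (any(start_bp > end_bp)) abort("mask intervals must have start_bp <= end_bp")
  fr <- cnv_frequency[!is.na(cnv_frequency)]
  if (any(fr < 0 | fr > 1)) abort("cnv_frequency must lie in [0, 1]")
  out <- tibble(
    chromosome = as.character(chromosome), start_bp = as.integer(start_bp),
    end_bp = as.integer(end_bp), kind = kind,
    cnv_frequency = as.numeric(cnv_frequency)
  )
  class(out) <- c("region_mask", class(out))
  out
}

loci_in_mask <- function(loci, mask, kinds) {
  mk <- mask[mask$kind %in% kinds, , drop = FALSE]
  hit <- rep(FALSE, nrow(loci))
  if (nrow(mk) == 0) return(hit)
  for (chr in unique(mk$chromosome)) {
    sel <- loci$chromosome == chr
    if (!any(sel)) next
    q <- IRanges::IRanges(start = loci$position_bp[sel], width = 1L)
    s <- mk[mk$chromosome == chr, ]
    subj <- IRanges::IRanges(start = s$start_bp, end = s$end_bp)
    hit[sel] <- IRanges::overlapsAny(q, subj)
  }
  hit
}

#' Remove loci intersecting masked regions
#'
#' Loci inside any immunoglobulin-variable interval, or inside any CNV
#' interval whose frequency meets `cnv_freq_threshold`, are removed from the
#' panel.  An empty mask is the identity.
#'
#' @param gm A [genotype_matrix()].
#' @param mask A [region_mask()].
#' @param cnv_freq_threshold CNV intervals with frequency `>=` this value
#'   trigger removal (default 0.05).
#' @return A filtered [genotype_matrix()] with attribute `mask_removed`
#'   giving removal counts per kind.
#' @export
apply_region_mask <- function(gm, mask, cnv_freq_threshold = 0.05) {
  if (nrow(mask) == 0) return(gm)
  cnv <- mask[mask$kind == "cnv" &
                !is.na(mask$cnv_frequency) &
                mask$cnv_frequency >= cnv_freq_threshold, , drop = FALSE]
  hit_igv <- loci_in_mask(gm$loci, mask, "igv")
  hit_cnv <- loci_in_mask(gm$loci, cnv, "cnv")
  out <- subset_genotypes(gm, loci = !(hit_igv | hit_cnv))
  attr(out, "mask_removed") <- c(igv = sum(hit_igv), cnv = sum(hit_cnv & !hit_igv))
  out
}

#' Per-locus homozygosity frequency (Freq_HOM)
#'
#' The fraction of non-missing calls that are homozygous at each locus.
#' With `scope = "pooled"` all samples are pooled (the basis of the
#' cross-population HPS); with `scope = "per_population"` one column is
#' returned per population (the basis of the within-population HPS).
#'
#' @param gm A [genotype_matrix()].
#' @param scope `"pooled"` or `"per_population"`.
#' @return A tibble with `locus_id`, and `freq_hom` (pooled) or one
#'   `freq_hom` per `population` row-group in long form.  Loci with no
#'   non-missing calls in scope get `NA`.
#' @export
compute_freq_hom <- function(gm, scope = c("pooled", "per_population")) {
  scope <- match.arg(scope)
  freq_of <- function(calls) {
    called <- colSums(calls != CALL_MISSING)
    hom <- colSums(calls == CALL_HOMREF | calls == CALL_HOMALT)
    unname(ifelse(called > 0, hom / called, NA_real_))
  }
  if (scope == "pooled") {
    return(tibble(locus_id = gm$loci$id, freq_hom = freq_of(gm$calls)))
  }
  pops <- unique(gm$samples$population)
  purrr::map_dfr(pops, function(p) {
    tibble(
      population = p,
      locus_id = gm$loci$id,
      freq_hom = freq_of(gm$calls[gm$samples$population == p, , drop = FALSE])
    )
  })
}

#' Per-locus QC report
#'
#' @param gm A [genotype_matrix()].
#' @param mask Optional [region_mask()].
#' @return A tibble with locus id, position, MAF, HWE exact p-value, and
#'   mask intersection flags.
#' @export
qc_report <- function(gm, mask = NULL) {
  cc <- locus_call_counts(gm)
  m <- locus_maf(gm)
  p <- vapply(seq_len(nrow(cc)), function(i) {
    if (cc$n_homref[i] + cc$n_het[i] + cc$n_homalt[i] == 0) return(NA_real_)
    hwe_exact_test(cc$n_homref[i], cc$n_het[i], cc$n_homalt[i])
  }, numeric(1))
  out <- tibble(
    locus_id = gm$loci$id,
    chromosome = gm$loci$chromosome,
    position_bp = gm$loci$position_bp,
    maf = m$maf,
    hwe_p = p
  )
  if (!is.null(mask)) {
    out$in_igv <- loci_in_mask(gm$loci, mask, "igv")
    out$in_cnv <- loci_in_mask(gm$loci, mask, "cnv")
    out$in_abnormality <- loci_in_mask(gm$loci, mask, "abnormality")
  }
  out
}

#' Restrict chromosome X to female samples
#'
#' Segment detection on chromosome X uses female genotypes only; male
#' (hemizygous) calls are set to missing unless `include_males = TRUE`.
#'
#' @param gm A [genotype_matrix()].
#' @param x_chromosome Label of the X chromosome in `loci$chromosome`.
#' @param include_males Keep male X genotypes as-is (off by default).
#' @return A [genotype_matrix()].
#' @export
mask_male_chrx <- function(gm, x_chromosome = "X", include_males = FALSE) {
  if (include_males) return(gm)
  xcols <- gm$loci$chromosome == x_chromosome
  males <- gm$samples$sex == "male"
  if (any(xcols) && any(males)) {
    gm$calls[males, xcols] <- CALL_MISSING
  }
  gm
}
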