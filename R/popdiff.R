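#' Two-population moment estimator of Fst (theta)
#'
#' Weir-Cockerham-style genotype-frequency moment estimator for two
#' populations with unequal sample sizes, computed from the
#' variance-component decomposition (among-population a, among-individual
#' b, within-individual c) of allele indicator variables; observed
#' heterozygote frequencies enter directly, so Hardy-Weinberg equilibrium
#' within populations is not assumed.  `theta = a / (a + b + c)`.
#'
#' The estimator is symmetric in the two populations and invariant to
#' allele relabelling.  It equals 1 when the populations are fixed for
#' opposite alleles and is near 0 (small-sample bias only, possibly
#' negative) for identical genotype frequencies.  Negative estimates are
#' returned as computed.
#'
#' @param counts_a,counts_b Length-3 genotype count vectors
#'   `(homRef, het, homAlt)`; both populations must be non-empty.
#' @return `theta`, or `NA` when undefined (both populations monomorphic
#'   for the same allele, or a single individual per population).
#' @export
fst_theta <- function(counts_a, counts_b) {
  comp <- fst_components(counts_a, counts_b)
  if (is.na(comp[["a"]])) return(NA_real_)
  tot <- comp[["a"]] + comp[["b"]] + comp[["c"]]
  if (tot == 0) return(NA_real_)
  comp[["a"]] / tot
}

# Weir-Cockerham (1984) a/b/c variance components for two populations,
# one biallelic locus.
fst_components <- function(counts_a, counts_b) {
  n1 <- sum(counts_a); n2 <- sum(counts_b)
  if (n1 == 0 || n2 == 0) abort("both populations need at least one genotype")
  if (n1 < 2 && n2 < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  r <- 2
  p1 <- (2 * counts_a[1] + counts_a[2]) / (2 * n1)
  p2 <- (2 * counts_b[1] + counts_b[2]) / (2 * n2)
  h1 <- counts_a[2] / n1
  h2 <- counts_b[2] / n2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  if (nbar <= 1 || nc <= 0) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Per-locus theta between two populations of a genotype panel
#'
#' @param gm A [genotype_matrix()].
#' @param pop_a,pop_b Population labels.
#' @return A tibble: `locus_id`, `chromosome`, `position_bp`, genotype
#'   counts, `theta` (`NA` where undefined).
#' @export
fst_scan <- function(gm, pop_a, pop_b) {
  ga <- gm$calls[gm$samples$population == pop_a, , drop = FALSE]
  gb <- gm$calls[gm$samples$population == pop_b, , drop = FALSE]
  cnt <- function(g) {
    rbind(colSums(g == CALL_HOMREF), colSums(g == CALL_HET),
          colSums(g == CALL_HOMALT))
  }
  ca <- cnt(ga); cb <- cnt(gb)
  theta <- vapply(seq_len(ncol(ca)), function(j) {
    if (sum(ca[, j]) == 0 || sum(cb[, j]) == 0) return(NA_real_)
    fst_theta(ca[, j], cb[, j])
  }, numeric(1))
  tibble(
    locus_id = gm$loci$id,
    chromosome = gm$loci$chromosome,
    position_bp = gm$loci$position_bp,
    theta = theta
  )
}

#' Mean theta over the loci of a peak
#'
#' @param peak One peak row (`chromosome`, `low_valley_bp`,
#'   `high_valley_bp`).
#' @param locus_theta Output of [fst_scan()] (one comparison population);
#'   undefined loci are excluded.
#' @return Mean theta, or `NA` when no defined locus lies in the peak.
#' @export
peak_fst <- function(peak, locus_theta) {
  sel <- locus_theta$chromosome == peak$chromosome &
    locus_theta$position_bp >= peak$low_valley_bp &
    locus_theta$position_bp <= peak$high_valley_bp &
    !is.na(locus_theta$theta)
  if (!any(sel)) return(NA_real_)
  mean(locus_theta$theta[sel])
}

#' Extract differentiated high-homozygosity peaks between two populations
#'
#' Selects peaks whose maximum ext_AUC rank reaches `rank_min` in both
#' populations and whose mean theta exceeds the chromosome-type threshold;
#' for each selected peak the loci with extreme theta (above the same
#' threshold) are extracted, alleles oriented so the pooled minor allele is
#' counted, and each population's haplotype frequency estimated as the
#' average minor-allele frequency across those loci.
#'
#' @param peaks Peak tibble with `chromosome`, `low_valley_bp`,
#'   `high_valley_bp`, `height`.
#' @param tracks Named list (or combined tibble) of rank tracks from
#'   [ext_auc_rank()] for the two populations.
#' @param locus_theta Output of [fst_scan()] between the two populations.
#' @param gm The [genotype_matrix()] (for allele frequencies).
#' @param pop_a,pop_b The two population labels.
#' @param rank_min Minimum cross-population rank (default 0.90).
#' @param theta_autosome,theta_chrx Selection thresholds (defaults 0.0360
#'   and 0.0538).
#' @param x_chromosome Chromosome label treated as X.
#' @return A tibble of selected peaks with `n_extreme`, `prop_extreme`,
#'   `freq_a`, `freq_b`, `freq_diff`, `mean_theta`; peaks with no
#'   qualifying loci are dropped.
#' @export
differentiated_peaks <- function(peaks, tracks, locus_theta, gm,
                                 pop_a, pop_b, rank_min = 0.90,
                                 theta_autosome = 0.0360,
                                 theta_chrx = 0.0538,
                                 x_chromosome = "X") {
  if (nrow(peaks) == 0) return(peaks)
  rows_a <- gm$samples$population == pop_a
  rows_b <- gm$samples$population == pop_b
  out <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    pk <- peaks[i, ]
    thr <- if (pk$chromosome == x_chromosome) theta_chrx else theta_autosome
    ranks <- cross_population_rank(pk, tracks)
    if (any(is.na(ranks)) || any(ranks < rank_min)) return(NULL)
    sel <- locus_theta$chromosome == pk$chromosome &
      locus_theta$position_bp >= pk$low_valley_bp &
      locus_theta$position_bp <= pk$high_valley_bp &
      !is.na(locus_theta$theta)
    if (!any(sel)) return(NULL)
    mean_theta <- mean(locus_theta$theta[sel])
    if (mean_theta <= thr) return(NULL)
    extreme <- sel & locus_theta$theta > thr
    if (!any(extreme)) return(NULL)
    loc_ix <- match(locus_theta$locus_id[extreme], gm$loci$id)
    af <- function(rows, j) {
      g <- gm$calls[rows, j]
      g <- g[g != CALL_MISSING]
      if (length(g) == 0) return(NA_real_)
      # frequency of the alternate allele
      (2 * sum(g == CALL_HOMALT) + sum(g == CALL_HET)) / (2 * length(g))
    }
    fa <- vapply(loc_ix, function(j) af(rows_a, j), numeric(1))
    fb <- vapply(loc_ix, function(j) af(rows_b, j), numeric(1))
    # orient to the pooled minor allele
    pooled <- (fa + fb) / 2
    flip <- !is.na(pooled) & pooled > 0.5
    fa[flip] <- 1 - fa[flip]
    fb[flip] <- 1 - fb[flip]
    tibble(
      pk[, intersect(c("population", "chromosome", "apex_bp", "low_valley_bp",
                       "high_valley_bp", "height"), names(pk))],
      n_extreme = sum(extreme),
      prop_extreme = sum(extreme) / sum(sel),
      mean_theta = mean_theta,
      freq_a = mean(fa, na.rm = TRUE),
      freq_b = mean(fb, na.rm = TRUE),
      freq_diff = abs(mean(fa, na.rm = TRUE) - mean(fb, na.rm = TRUE))
    )
  })
  out
}
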