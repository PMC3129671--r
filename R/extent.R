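#' Build an intersecting segment length matrix (ISLM)
#'
#' A samples-by-loci matrix for one chromosome in which cell (s, l) holds
#' the length of the segment of sample s covering locus l (0 when no
#' segment intersects).  Cells under CNV/abnormality-masked segments are
#' set to `NA` ("missing").  Segments are filtered to
#' `HPS_ex <= filter_hps` when that score is available.
#'
#' @param segments Segment tibble (from [detect_segments()], ideally
#'   [annotate_segments()]).
#' @param gm The [genotype_matrix()].
#' @param chromosome Chromosome to build (default: the single chromosome
#'   present).
#' @param units `"bp"` or `"cm"`; centimorgan lengths require `arm_rates`.
#' @param arm_rates Arm recombination-rate table (see [read_arm_rates()]).
#' @param filter_hps Keep segments with `hps_ex` at or below this value
#'   (default 0.01; `Inf` disables).
#' @return An object of class `hz_islm` with fields `values`, `capped`,
#'   `units`, `chromosome`, `loci`, `samples`.
#' @export
build_islm <- function(segments, gm, chromosome = NULL,
                       units = c("bp", "cm"), arm_rates = NULL,
                       filter_hps = 0.01) {
  units <- match.arg(units)
  if (is.null(chromosome)) {
    chromosome <- unique(segments$chromosome)
    if (length(chromosome) != 1) abort("specify `chromosome` for multi-chromosome input")
  }
  if (units == "cm" && is.null(arm_rates)) abort("cm units require `arm_rates`")
  sel <- gm$loci$chromosome == chromosome
  loci <- gm$loci[sel, ]
  segs <- segments[segments$chromosome == chromosome, ]
  if ("hps_ex" %in% names(segs) && is.finite(filter_hps)) {
    segs <- segs[segs$hps_ex <= filter_hps, ]
  }
  n_s <- nrow(gm$samples); n_l <- nrow(loci)
  values <- matrix(0, n_s, n_l, dimnames = list(gm$samples$id, loci$id))
  capped <- matrix(FALSE, n_s, n_l)
  seg_ids <- matrix(NA_integer_, n_s, n_l)
  row_of <- setNames(seq_len(n_s), gm$samples$id)
  lens <- if (units == "bp") as.numeric(segs$length_bp) else
    segments_cm(segs, arm_rates)
  has_mask <- "masked_cnv" %in% names(segs)
  for (i in seq_len(nrow(segs))) {
    r <- row_of[segs$sample_id[i]]
    cols <- segs$start_idx[i]:segs$end_idx[i]
    masked <- has_mask && isTRUE(segs$masked_cnv[i])
    values[r, cols] <- if (masked) NA_real_ else lens[i]
    seg_ids[r, cols] <- i
  }
  structure(
    list(values = values, capped = capped, seg_ids = seg_ids,
         seg_index = segs, units = units,
         chromosome = chromosome, loci = loci, samples = gm$samples),
    class = "hz_islm"
  )
}

#' @export
print.hz_islm <- function(x, ...) {
  cat(sprintf("<hz_islm> chr %s: %d samples x %d loci (%s)\n",
              x$chromosome, nrow(x$values), ncol(x$values), x$units))
  invisible(x)
}

#' Tidy an ISLM into long form
#'
#' @param x An `hz_islm`.
#' @param ... Unused.
#' @return A tibble with one row per (sample, locus) cell.
#' @export
tidy.hz_islm <- function(x, ...) {
  tibble(
    sample_id = rep(x$samples$id, times = ncol(x$values)),
    population = rep(x$samples$population, times = ncol(x$values)),
    locus_id = rep(x$loci$id, each = nrow(x$values)),
    position_bp = rep(x$loci$position_bp, each = nrow(x$values)),
    length = as.numeric(x$values),
    capped = as.logical(x$capped)
  )
}

#' Convert a physical length to centimorgans at an arm-average rate
#'
#' @param length_bp Length in base pairs.
#' @param cm_per_mb Arm-average recombination rate.
#' @return Length in centimorgans.
#' @export
bp_to_cm <- function(length_bp, cm_per_mb) {
  length_bp * cm_per_mb / 1e6
}

#' Genetic length of an interval under arm-average rates
#'
#' The interval is intersected with the chromosome's arm intervals and each
#' overlapping piece converted at that arm's average rate, so segments
#' spanning the arm boundary are split proportionally.
#'
#' @param chromosome Chromosome label.
#' @param start_bp,end_bp Interval (1-based inclusive).
#' @param arm_rates Table with columns `chromosome`, `arm`, `start_bp`,
#'   `end_bp`, `cm_per_mb`.
#' @return Length in centimorgans.
#' @export
interval_cm <- function(chromosome, start_bp, end_bp, arm_rates) {
  arms <- arm_rates[arm_rates$chromosome == chromosome, ]
  if (nrow(arms) == 0) abort(sprintf("no arm rates for chromosome %s", chromosome))
  ov_start <- pmax(arms$start_bp, start_bp)
  ov_end <- pmin(arms$end_bp, end_bp)
  ov <- pmax(0, ov_end - ov_start + 1)
  if (sum(ov) < end_bp - start_bp + 1) {
    abort(sprintf("interval %s:%d-%d not fully covered by arm table",
                  chromosome, start_bp, end_bp))
  }
  sum(bp_to_cm(ov, arms$cm_per_mb))
}

#' Genetic lengths for a whole segment table
#'
#' Vectorised [interval_cm()] over the rows of a segment tibble.
#'
#' @param segments Tibble with `chromosome`, `start_bp`, `end_bp`.
#' @param arm_rates Arm recombination-rate table.
#' @return Numeric vector of centimorgan lengths.
#' @export
segments_cm <- function(segments, arm_rates) {
  out <- numeric(nrow(segments))
  for (i in seq_len(nrow(arm_rates))) {
    arm <- arm_rates[i, ]
    ov <- pmax(0, pmin(segments$end_bp, arm$end_bp) -
                 pmax(segments$start_bp, arm$start_bp) + 1)
    ov[segments$chromosome != arm$chromosome] <- 0
    out <- out + bp_to_cm(ov, arm$cm_per_mb)
  }
  covered <- vapply(unique(segments$chromosome), function(chr) {
    any(arm_rates$chromosome == chr)
  }, logical(1))
  if (!all(covered)) abort("arm table missing a chromosome")
  out
}

#' Cap ISLM cells fed by putatively autozygous segments
#'
#' Cells whose segment has a MAD score above the threshold are replaced,
#' per locus column, with the highest non-autozygous length in that column
#' ("capped"); a column holding only autozygous values is set to 0 and
#' counted.  This removes the leverage of rare very long autozygous
#' segments on the extent measures without discarding the carrier samples.
#'
#' @param islm An `hz_islm` built from segments that carry `mad_score`.
#' @param mad_threshold Capping threshold (default 10).
#' @return The capped `hz_islm`; attribute `n_zeroed_columns` counts
#'   columns with no non-autozygous value.
#' @export
mask_islm_autozygous <- function(islm, mad_threshold = 10) {
  segs <- islm$seg_index
  if (!"mad_score" %in% names(segs)) {
    abort("ISLM segments lack mad_score; run annotate_segments() first")
  }
  auto <- which(segs$mad_score > mad_threshold)
  if (length(auto) == 0) return(islm)
  auto_cell <- matrix(islm$seg_ids %in% auto, nrow(islm$values))
  n_zeroed <- 0L
  for (j in which(colSums(auto_cell) > 0)) {
    col <- islm$values[, j]
    non_auto <- col[!auto_cell[, j] & !is.na(col)]
    cap <- if (length(non_auto) == 0) { n_zeroed <- n_zeroed + 1L; 0 } else max(non_auto)
    rows <- auto_cell[, j] & !is.na(col)
    islm$values[rows, j] <- cap
    islm$capped[rows, j] <- TRUE
  }
  if (n_zeroed > 0) {
    inform(sprintf("mask_islm_autozygous: %d column(s) had only autozygous values; set to 0", n_zeroed))
  }
  attr(islm, "n_zeroed_columns") <- n_zeroed
  islm
}

#' Percentile-extent matrix (PE_mat)
#'
#' Per locus, the 101 percentiles (0, 1, ..., 100) of one population's
#' intersecting-segment-length vector, under the linear-interpolation
#' (type 7) quantile definition.  Masked (`NA`) cells are dropped; zeros
#' (samples without a covering segment) are retained.  A locus with all
#' cells masked yields a row of `NA`.
#'
#' @param islm An `hz_islm` (typically after [mask_islm_autozygous()]).
#' @param population Population label to summarise.
#' @return An object of class `hz_pemat`: fields `values` (loci x 101),
#'   `percentiles`, `population`, `units`, `loci`.
#' @export
pe_mat <- function(islm, population) {
  rows <- islm$samples$population == population
  if (!any(rows)) abort(sprintf("no samples in population %s", population))
  probs <- seq(0, 1, by = 0.01)
  vals <- t(apply(islm$values[rows, , drop = FALSE], 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(rep(NA_real_, length(probs)))
    quantile(v, probs = probs, type = 7, names = FALSE)
  }))
  dimnames(vals) <- list(islm$loci$id, paste0("p", 0:100))
  structure(
    list(values = vals, percentiles = 0:100, population = population,
         units = islm$units, chromosome = islm$chromosome, loci = islm$loci),
    class = "hz_pemat"
  )
}

#' @export
print.hz_pemat <- function(x, ...) {
  cat(sprintf("<hz_pemat> chr %s, %s: %d loci x 101 percentiles (%s)\n",
              x$chromosome, x$population, nrow(x$values), x$units))
  invisible(x)
}

#' Tidy a percentile-extent matrix into long form
#'
#' @param x An `hz_pemat`.
#' @param ... Unused.
#' @return A tibble with one row per (locus, percentile).
#' @export
tidy.hz_pemat <- function(x, ...) {
  tibble(
    locus_id = rep(x$loci$id, times = 101),
    position_bp = rep(x$loci$position_bp, times = 101),
    percentile = rep(0:100, each = nrow(x$values)),
    value = as.numeric(x$values)
  )
}

# Exact integral of a right-continuous ECDF step function over [lower, upper].
ecdf_step_integral <- function(values, lower, upper) {
  if (upper <= lower) return(0)
  F <- ecdf(values)
  knots <- sort(unique(values))
  pts <- sort(unique(c(lower, upper, knots[knots > lower & knots < upper])))
  widths <- diff(pts)
  sum(F(pts[-length(pts)]) * widths)
}

#' ext_AUC: locus-level extent of overlapping homozygosity
#'
#' For each locus, the intersecting-segment-length values of all samples
#' are sign-reversed (so the rarer, longer segments start the distribution)
#' and the integration bounds are taken from that combined reversed vector:
#' the lower bound is its most-negative value and the upper bound the value
#' closest to zero from below (the empty interval between that value and
#' zero is excluded as noise).  The population's reversed values (zeros
#' included, masked cells dropped) define an ECDF whose exact step-function
#' integral over the bounds is the locus's ext_AUC.  A locus with no
#' intersecting segment in any sample scores 0.
#'
#' @param islm An `hz_islm` holding all populations' samples (centimorgan
#'   units in the standard workflow).
#' @param population Population whose ECDF is integrated.
#' @return A tibble of class `hz_exttrack`: `locus_id`, `chromosome`,
#'   `position_bp`, `population`, `ext_auc`.
#' @export
ext_auc <- function(islm, population) {
  rows <- islm$samples$population == population
  if (!any(rows)) abort(sprintf("no samples in population %s", population))
  vals <- vapply(seq_len(ncol(islm$values)), function(j) {
    all_v <- islm$values[, j]
    all_v <- all_v[!is.na(all_v)]
    rev_all <- -all_v
    neg <- rev_all[rev_all < 0]
    if (length(neg) == 0) return(0)
    lower <- min(neg)
    upper <- max(neg)
    pv <- islm$values[rows, j]
    pv <- pv[!is.na(pv)]
    if (length(pv) == 0) return(0)
    ecdf_step_integral(-pv, lower, upper)
  }, numeric(1))
  out <- tibble(
    locus_id = islm$loci$id,
    chromosome = islm$chromosome,
    position_bp = islm$loci$position_bp,
    population = population,
    ext_auc = vals
  )
  class(out) <- c("hz_exttrack", class(out))
  out
}

#' Rank ext_AUC values within a chromosome-population
#'
#' Each value is replaced by its empirical cumulative probability
#' `rank(x) = #(values <= x) / n` over the chromosome's loci for that
#' population, so the maximum value has rank 1.
#'
#' @param track An ext_AUC track from [ext_auc()].
#' @return The track with a `rank` column added.
#' @export
ext_auc_rank <- function(track) {
  track |>
    group_by(.data$chromosome, .data$population) |>
    mutate(rank = ecdf(.data$ext_auc)(.data$ext_auc)) |>
    ungroup()
}
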