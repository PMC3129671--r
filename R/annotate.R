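#' Homozygosity probability score for one segment
#'
#' The product, over a segment's constituent loci, of the per-locus observed
#' homozygosity frequency (Freq_HOM).  Computed in log space so that
#' multi-thousand-SNP segments do not underflow.  With pooled frequencies
#' this is the cross-population HPS (`HPS_ex`, the default downstream filter
#' keeps `HPS_ex <= 0.01`); with the sample's own population's frequencies
#' it is the within-population HPS (`HPS_in`).
#'
#' @param freq_hom Vector of Freq_HOM values for the segment's loci; any
#'   `NA` is an error naming the offending position.
#' @return The probability (0, 1].
#' @export
hps <- function(freq_hom) {
  if (anyNA(freq_hom)) {
    abort(sprintf("missing Freq_HOM at locus index %d", which(is.na(freq_hom))[1]))
  }
  exp(sum(log(freq_hom)))
}

segment_locus_index <- function(segments, loci) {
  # map per-chromosome start/end indices to global locus row indices
  offsets <- cumsum(c(0, rle(loci$chromosome)$lengths))
  names(offsets) <- c(rle(loci$chromosome)$values, "")
  offsets[segments$chromosome]
}

#' Annotate segments with HPS, MAD score and founder haplotype frequency
#'
#' Convenience wrapper running [hps()] (both scopes), [mad_score()] against
#' a bp-unit ISLM, and [founder_hap_freq()] against a phased panel, adding
#' columns `hps_ex`, `hps_in`, `mad_score`, `founder_hap_freq`,
#' `putative_autozygous` (MAD score above `mad_threshold`) and
#' `autozygous_call` (additionally zero founder-haplotype frequency).
#' MAD scores and founder frequencies are computed for the segments that
#' pass the `HPS_ex` filter -- the set that enters all downstream extent
#' analyses; segments filtered out as chance homozygosity keep `NA`.
#'
#' @param segments Segments from [detect_segments()].
#' @param gm The [genotype_matrix()] they were detected in.
#' @param panel Optional [phased_panel()] for founder-haplotype frequency.
#' @param mad_threshold MAD score above which a segment is flagged
#'   putatively autozygous (default 10).
#' @param hps_filter `HPS_ex` cutoff defining the analysis set
#'   (default 0.01; `Inf` annotates every segment).
#' @return The segment tibble with score columns added.
#' @export
annotate_segments <- function(segments, gm, panel = NULL, mad_threshold = 10,
                              hps_filter = 0.01) {
  fh_ex <- compute_freq_hom(gm, "pooled")$freq_hom
  fh_in <- compute_freq_hom(gm, "per_population")
  pops <- unique(gm$samples$population)
  fh_in_mat <- vapply(pops, function(p) {
    fh_in$freq_hom[fh_in$population == p]
  }, numeric(ncol(gm$calls)))
  off <- segment_locus_index(segments, gm$loci)
  gs <- off + segments$start_idx
  ge <- off + segments$end_idx
  hps_span <- function(fh) {
    cs_na <- c(0L, cumsum(is.na(fh)))
    if (any(cs_na[ge + 1L] - cs_na[gs] > 0)) {
      bad <- which(cs_na[ge + 1L] - cs_na[gs] > 0)[1]
      abort(sprintf("missing Freq_HOM within segment %d", bad))
    }
    lf <- log(fh); lf[is.na(lf)] <- 0
    cl <- c(0, cumsum(lf))
    exp(cl[ge + 1L] - cl[gs])
  }
  segments$hps_ex <- hps_span(fh_ex)
  segments$hps_in <- NA_real_
  for (p in pops) {
    rows <- segments$population == p
    if (any(rows)) {
      segments$hps_in[rows] <- hps_span(fh_in_mat[, p])[rows]
    }
  }
  # MAD score against the HPS-filtered bp ISLM of each chromosome
  in_set <- segments$hps_ex <= hps_filter
  segments$mad_score <- NA_real_
  for (chr in unique(segments$chromosome)) {
    sel <- segments$chromosome == chr & in_set
    if (!any(sel)) next
    islm_chr <- build_islm(segments[segments$chromosome == chr & in_set, ],
                           gm, chromosome = chr, units = "bp",
                           filter_hps = Inf)
    segments$mad_score[sel] <- vapply(which(sel), function(i) {
      mad_score(segments$length_bp[i],
                islm_chr$values[, segments$start_idx[i]:segments$end_idx[i],
                                drop = FALSE],
                islm_chr$samples$population == segments$population[i])
    }, numeric(1))
  }
  segments$putative_autozygous <- !is.na(segments$mad_score) &
    segments$mad_score > mad_threshold
  if (!is.null(panel)) {
    segments$founder_hap_freq <- NA_real_
    segments$founder_hap_freq[in_set] <- vapply(which(in_set), function(i) {
      ix <- (off[i] + segments$start_idx[i]):(off[i] + segments$end_idx[i])
      founder_hap_freq(
        gm$calls[segments$sample_id[i], ix],
        panel, ix,
        population = segments$population[i],
        exclude_sample = segments$sample_id[i]
      )
    }, numeric(1))
    segments$autozygous_call <- segments$putative_autozygous &
      !is.na(segments$founder_hap_freq) & segments$founder_hap_freq == 0
  }
  segments
}

#' Minimum inclusive segment length (MISL)
#'
#' For each chromosome, the longest segment of each sample is found and the
#' smallest of those maxima is the chromosome's MISL; the genome-wide MISL
#' is the minimum over chromosomes.  Filtering at MISL guarantees every
#' sample contributes at least one segment at the threshold.  Samples with
#' no segment on a chromosome are skipped for that chromosome with a
#' warning.
#'
#' @param segments A segment tibble.
#' @param subsets Optional named list of chromosome vectors; for each, the
#'   minimum member MISL is reported.
#' @return A list with `misl_chr` (tibble chromosome/misl_bp), `misl_gw`,
#'   and `misl_subset` (named numeric, if requested).
#' @export
compute_misl <- function(segments, subsets = NULL) {
  samp <- unique(segments$sample_id)
  per <- segments |>
    group_by(.data$chromosome, .data$sample_id) |>
    summarise(max_len = max(.data$length_bp), .groups = "drop")
  incomplete <- per |>
    group_by(.data$chromosome) |>
    summarise(n = dplyr::n_distinct(.data$sample_id), .groups = "drop")
  if (any(incomplete$n < length(samp))) {
    warn(sprintf(
      "compute_misl: %d chromosome(s) missing segments for some samples; those samples skipped",
      sum(incomplete$n < length(samp))
    ))
  }
  misl_chr <- per |>
    group_by(.data$chromosome) |>
    summarise(misl_bp = min(.data$max_len), .groups = "drop")
  out <- list(
    misl_chr = misl_chr,
    misl_gw = min(misl_chr$misl_bp)
  )
  if (!is.null(subsets)) {
    out$misl_subset <- vapply(subsets, function(chrs) {
      min(misl_chr$misl_bp[misl_chr$chromosome %in% chrs])
    }, numeric(1))
  }
  out
}

#' Robust MAD score of a segment's length against the local distribution
#'
#' The intersecting-segment-length vectors (ISLVs) under the segment are
#' extracted and duplicate columns collapsed to one representative.  For
#' each representative the median `m` and raw median absolute deviation `d`
#' of the non-zero values are computed and the per-vector score is
#' `(length - m) / (1.4826 * d)`, a robust z-score under the normal
#' consistency constant.  The segment's score is the median of the
#' per-vector scores.  When `d = 0` the score is `+Inf` if the length
#' exceeds `m` and 0 otherwise; all-zero vectors are skipped.
#'
#' @param length_value The segment's length (same units as the ISLM).
#' @param islv_block Matrix of ISLV columns under the segment (samples in
#'   rows).
#' @param pop_rows Logical vector selecting the rows of the segment's
#'   population (defaults to all rows).
#' @return The MAD score (`NA` if no usable vector).
#' @export
mad_score <- function(length_value, islv_block,
                      pop_rows = rep(TRUE, nrow(islv_block))) {
  block <- islv_block[pop_rows, , drop = FALSE]
  reps <- !duplicated(t(block))
  block <- block[, reps, drop = FALSE]
  scores <- vapply(seq_len(ncol(block)), function(j) {
    v <- block[, j]
    v <- v[!is.na(v) & v > 0]
    if (length(v) == 0) return(NA_real_)
    m <- median(v)
    d <- median(abs(v - m))
    if (d == 0) {
      if (length_value > m) Inf else 0
    } else {
      (length_value - m) / (1.4826 * d)
    }
  }, numeric(1))
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) return(NA_real_)
  median(scores)
}

#' Phased haplotype panel
#'
#' A matrix of haplotype allele codes (0/1, `NA` = missing), two rows per
#' diploid sample, aligned with a genotype panel's loci.
#'
#' @param haplotypes Integer matrix, `2 * n_samples` rows by `n_loci`
#'   columns, values 0/1/`NA`.
#' @param sample_id Character vector of length `nrow(haplotypes)` linking
#'   each row to its diploid sample.
#' @param population Population label per row.
#' @return An object of class `phased_panel`.
#' @export
phased_panel <- function(haplotypes, sample_id, population) {
  haplotypes <- as.matrix(haplotypes)
  if (nrow(haplotypes) %% 2 != 0) abort("phased panel must have an even row count")
  stopifnot(length(sample_id) == nrow(haplotypes),
            length(population) == nrow(haplotypes))
  structure(
    list(haplotypes = haplotypes, sample_id = sample_id,
         population = population),
    class = "phased_panel"
  )
}

#' @export
print.phased_panel <- function(x, ...) {
  cat(sprintf("<phased_panel> %d haplotypes x %d loci\n",
              nrow(x$haplotypes), ncol(x$haplotypes)))
  invisible(x)
}

#' Founder haplotype frequency of a homozygous segment
#'
#' The segment's founder haplotype is its homozygous allele string
#' (heterozygous and missing loci excluded).  Mismatches against every
#' panel haplotype restricted to the segment's loci are counted (missing
#' panel alleles are excluded from the comparison), and the frequency is
#' the proportion of panel haplotypes within the tolerance
#' `max(0.01 * L, 1)` mismatches, where `L` is the segment's SNP count.
#'
#' @param calls The segment's call vector (codes 0/1/2/3).
#' @param panel A [phased_panel()].
#' @param locus_index Column indices of the segment's loci in the panel.
#' @param population Optional population label restricting the panel.
#' @param exclude_sample Optional sample id whose haplotypes are excluded
#'   (the segment's own carrier, so that a haplotype private to that
#'   sample scores 0).
#' @return Frequency in `[0, 1]`.
#' @export
founder_hap_freq <- function(calls, panel, locus_index,
                             population = NULL, exclude_sample = NULL) {
  if (any(locus_index > ncol(panel$haplotypes))) {
    abort("segment loci absent from phased panel")
  }
  keep <- rep(TRUE, nrow(panel$haplotypes))
  if (!is.null(population)) keep <- keep & panel$population == population
  if (!is.null(exclude_sample)) keep <- keep & panel$sample_id != exclude_sample
  hap <- panel$haplotypes[keep, locus_index, drop = FALSE]
  hom <- calls == CALL_HOMREF | calls == CALL_HOMALT
  founder <- ifelse(calls[hom] == CALL_HOMALT, 1L, 0L)
  hap <- hap[, hom, drop = FALSE]
  L <- length(founder)
  if (L == 0 || nrow(hap) == 0) return(0)
  tol <- max(0.01 * L, 1)
  mism <- colSums(t(hap) != founder, na.rm = TRUE)
  mean(mism <= tol)
}

#' Mappable chromosome length
#'
#' The span between the first and last SNP minus the summed length of
#' inter-SNP gaps larger than `gap_cutoff_bp`.
#'
#' @param positions Sorted base-pair positions (at least 2).
#' @param gap_cutoff_bp Gap size above which a gap is excluded
#'   (default 500 kb).
#' @return Length in bp.
#' @export
mappable_length <- function(positions, gap_cutoff_bp = 5e5) {
  if (length(positions) < 2) abort("need at least 2 loci")
  gaps <- diff(sort(positions))
  max(positions) - min(positions) - sum(gaps[gaps > gap_cutoff_bp])
}

#' Cumulative chromosome coverage curves by segment length
#'
#' Per individual and chromosome, segments are sorted by length, their
#' lengths cumulated, the cumulative sum linearly interpolated at the
#' requested length cutoffs and divided by the chromosome's mappable
#' length; the population median curve is returned.  Individuals whose
#' flagged (CNV-intersecting) segments carry more than
#' `max_flagged_snp_prop` of a chromosome's SNPs are excluded for that
#' chromosome, and flagged segments of retained individuals are dropped.
#' Callers should pre-filter segments to the density and `HPS_ex`
#' thresholds they intend (see [detect_segments()] flags and
#' [annotate_segments()]).
#'
#' @param segments Segment tibble (needs `masked_cnv` column if flag
#'   exclusion is wanted).
#' @param gm The [genotype_matrix()].
#' @param cutoffs Length grid in bp (default 0 to 1 Mb in 20 kb steps).
#' @param decreasing Sort segments by decreasing length before cumulating.
#' @param max_flagged_snp_prop Exclusion threshold (default 0.1).
#' @return A tibble: population, chromosome, cutoff_bp, median_proportion.
#' @export
coverage_curves <- function(segments, gm, cutoffs = seq(0, 1e6, by = 2e4),
                            decreasing = FALSE, max_flagged_snp_prop = 0.1) {
  has_flag <- "masked_cnv" %in% names(segments)
  purrr::map_dfr(unique(segments$chromosome), function(chr) {
    sel <- gm$loci$chromosome == chr
    mappable <- mappable_length(gm$loci$position_bp[sel])
    chr_snps <- sum(sel)
    sc <- segments[segments$chromosome == chr, ]
    per_ind <- purrr::map_dfr(unique(sc$sample_id), function(sid) {
      si <- sc[sc$sample_id == sid, ]
      if (has_flag) {
        flagged_snps <- sum(si$snp_count[si$masked_cnv])
        if (flagged_snps > max_flagged_snp_prop * chr_snps) return(NULL)
        si <- si[!si$masked_cnv, ]
      }
      lens <- sort(si$length_bp, decreasing = decreasing)
      cum <- cumsum(lens)
      at <- if (length(lens) == 0) rep(0, length(cutoffs)) else {
        if (decreasing) {
          # cumulative total of segments with length >= cutoff
          vapply(cutoffs, function(ct) {
            k <- sum(lens >= ct); if (k == 0) 0 else cum[k]
          }, numeric(1))
        } else {
          vapply(cutoffs, function(ct) {
            k <- sum(lens <= ct); if (k == 0) 0 else cum[k]
          }, numeric(1))
        }
      }
      tibble(
        population = si$population[1] %||% NA_character_,
        sample_id = sid, cutoff_bp = cutoffs,
        proportion = at / mappable
      )
    })
    if (nrow(per_ind) == 0) return(NULL)
    per_ind |>
      group_by(.data$population, .data$cutoff_bp) |>
      summarise(median_proportion = median(.data$proportion), .groups = "drop") |>
      mutate(chromosome = chr, .before = 1)
  })
}

#' Intersect two interval sets
#'
#' For each interval in `a`, the count and identities of intervals in `b`
#' overlapping it by at least one bp (1-based inclusive coordinates).
#' Calling with the arguments swapped gives the reverse comparison.
#'
#' @param a,b Tibbles with columns `chromosome`, `start_bp`, `end_bp`.
#' @return `a` with columns `n_hits` and `hits` (list of `b` row indices).
#' @export
intersect_segments <- function(a, b) {
  a$n_hits <- 0L
  a$hits <- vector("list", nrow(a))
  for (chr in unique(a$chromosome)) {
    ia <- which(a$chromosome == chr)
    ib <- which(b$chromosome == chr)
    if (length(ib) == 0) { a$hits[ia] <- list(integer()); next }
    qa <- IRanges::IRanges(a$start_bp[ia], a$end_bp[ia])
    qb <- IRanges::IRanges(b$start_bp[ib], b$end_bp[ib])
    ov <- IRanges::findOverlaps(qa, qb)
    hl <- split(ib[S4Vectors::subjectHits(ov)],
                factor(S4Vectors::queryHits(ov), levels = seq_along(ia)))
    a$hits[ia] <- unname(hl)
    a$n_hits[ia] <- lengths(hl)
  }
  a
}
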