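#' Smooth an ext_AUC track with a cubic smoothing spline
#'
#' A cubic smoothing spline with knot count equal to 3% of the loci
#' (rounded up, at least 4) is fitted to the values on the locus position
#' grid; the smoothing penalty itself is chosen by generalized
#' cross-validation.  The fitted values and analytic first derivative on
#' the locus grid are returned; sign changes of the derivative delineate
#' peaks and valleys.
#'
#' @param values Per-locus values (e.g. ext_AUC).
#' @param positions Base-pair positions (same length, at least 34 loci).
#' @return A tibble: `position_bp`, `value`, `smooth`, `deriv`.
#' @export
smooth_track <- function(values, positions) {
  n <- length(values)
  stopifnot(length(positions) == n)
  if (n < 34) {
    abort("too few loci to smooth (< 34); merge with a neighbouring window")
  }
  nknots <- max(4L, as.integer(ceiling(0.03 * n)))
  fit <- smooth.spline(positions, values, nknots = nknots, keep.data = FALSE)
  tibble(
    position_bp = positions,
    value = values,
    smooth = predict(fit, positions)$y,
    deriv = predict(fit, positions, deriv = 1)$y
  )
}

#' Detect peaks and valleys from a smoothed track
#'
#' Apexes are loci where the smoothed first derivative changes sign from
#' positive to negative; valleys where it changes from negative to
#' positive.  Each peak is bounded by its flanking valleys; chromosome
#' ends count as valleys.  Peak height is the smoothed value at the apex.
#'
#' @param smoothed Output of [smooth_track()].
#' @return A tibble of class `hz_peaks`: `apex_bp`, `low_valley_bp`,
#'   `high_valley_bp`, `height`, `low_valley_value`, `high_valley_value`,
#'   `apex_idx`, `low_valley_idx`, `high_valley_idx`.
#' @export
detect_peaks <- function(smoothed) {
  d <- smoothed$deriv
  n <- length(d)
  sgn <- sign(d)
  # index i marks a sign change between i and i+1
  apex <- which(sgn[-n] > 0 & sgn[-1] <= 0)
  valley <- which(sgn[-n] < 0 & sgn[-1] >= 0)
  # place the extremum at whichever neighbour has the more extreme value
  pick <- function(ix, take_max) {
    vapply(ix, function(i) {
      cand <- c(i, i + 1L)
      cand[if (take_max) which.max(smoothed$smooth[cand]) else
        which.min(smoothed$smooth[cand])]
    }, integer(1))
  }
  apex <- pick(apex, TRUE)
  valley <- pick(valley, FALSE)
  if (length(apex) == 0) {
    return(empty_peaks())
  }
  valley_all <- sort(unique(c(1L, valley, n)))
  out <- purrr::map_dfr(apex, function(a) {
    lo <- max(valley_all[valley_all <= a])
    hi <- min(valley_all[valley_all >= a])
    tibble(
      apex_bp = smoothed$position_bp[a],
      low_valley_bp = smoothed$position_bp[lo],
      high_valley_bp = smoothed$position_bp[hi],
      height = smoothed$smooth[a],
      low_valley_value = smoothed$smooth[lo],
      high_valley_value = smoothed$smooth[hi],
      apex_idx = a, low_valley_idx = lo, high_valley_idx = hi
    )
  })
  out <- arrange(out, .data$apex_bp)
  class(out) <- c("hz_peaks", class(out))
  out
}

empty_peaks <- function() {
  out <- tibble(
    apex_bp = integer(), low_valley_bp = integer(), high_valley_bp = integer(),
    height = numeric(), low_valley_value = numeric(),
    high_valley_value = numeric(), apex_idx = integer(),
    low_valley_idx = integer(), high_valley_idx = integer()
  )
  class(out) <- c("hz_peaks", class(out))
  out
}

#' Merge adjacent similar peaks
#'
#' Two directly adjacent peaks merge when their heights differ by less than
#' `tolerance` (relative to the taller) and the intervening valley is
#' within `tolerance` of the taller height; merging keeps the taller apex
#' and the outer valleys, and iterates to a fixpoint.
#'
#' @param peaks Peaks from [detect_peaks()], ordered by position.
#' @param tolerance Relative difference threshold (default 0.10).
#' @return The merged peak tibble.
#' @export
merge_peaks <- function(peaks, tolerance = 0.10) {
  if (nrow(peaks) <= 1) return(peaks)
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(peaks)) {
      h1 <- peaks$height[i]; h2 <- peaks$height[i + 1L]
      hmax <- max(h1, h2)
      v <- min(peaks$high_valley_value[i], peaks$low_valley_value[i + 1L])
      adjoining <- peaks$high_valley_idx[i] == peaks$low_valley_idx[i + 1L]
      if (adjoining && hmax > 0 &&
          abs(h1 - h2) / hmax < tolerance &&
          (hmax - v) / hmax < tolerance) {
        keep <- if (h1 >= h2) i else i + 1L
        new <- peaks[keep, ]
        new$low_valley_bp <- peaks$low_valley_bp[i]
        new$low_valley_value <- peaks$low_valley_value[i]
        new$low_valley_idx <- peaks$low_valley_idx[i]
        new$high_valley_bp <- peaks$high_valley_bp[i + 1L]
        new$high_valley_value <- peaks$high_valley_value[i + 1L]
        new$high_valley_idx <- peaks$high_valley_idx[i + 1L]
        peaks <- bind_rows(peaks[seq_len(i - 1L), ], new,
                           peaks[-seq_len(i + 1L), ])
        class(peaks) <- c("hz_peaks", class(tibble()))
        merged <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged) break
  }
  peaks
}

#' Flag outlier peaks by height
#'
#' A peak is an outlier when its height exceeds the upper whisker
#' (upper hinge + 1.5 times the inter-hinge spread, standard boxplot
#' statistics) of the chromosome's merged-peak heights.  With fewer than
#' 4 peaks no outliers are flagged and a warning is raised.
#'
#' @param peaks Merged peaks for one chromosome-population.
#' @return The peaks with a logical `outlier` column.
#' @export
flag_outlier_peaks <- function(peaks) {
  if (nrow(peaks) < 4) {
    if (nrow(peaks) > 0) warn("fewer than 4 peaks; no outliers flagged")
    peaks$outlier <- rep(FALSE, nrow(peaks))
    return(peaks)
  }
  fn <- fivenum(peaks$height)
  thr <- fn[4] + 1.5 * (fn[4] - fn[2])
  peaks$outlier <- peaks$height > thr
  peaks
}

#' Merge adjoining outlier peaks into peak regions
#'
#' Directly adjoining outlier peaks that are not well separated -- the
#' intervening valley exceeds half the smaller peak height -- are merged
#' into one region, iterating to a fixpoint.  The region spans from the
#' low valley of its first member to the high valley of its last.
#'
#' @param peaks Peaks with an `outlier` column (see
#'   [flag_outlier_peaks()]); only outliers form regions.
#' @param separation_factor Valley-to-height factor (default 0.5).
#' @return A tibble of regions: span, member count, summary statistics,
#'   and a `members` list column of member peak rows.
#' @export
merge_outlier_regions <- function(peaks, separation_factor = 0.5) {
  op <- peaks[peaks$outlier, , drop = FALSE]
  if (nrow(op) == 0) {
    return(tibble(
      start_bp = integer(), end_bp = integer(), n_peaks = integer(),
      max_height = numeric(), apex_bp = integer(), members = list()
    ))
  }
  op <- arrange(op, .data$apex_bp)
  grp <- 1L
  group <- integer(nrow(op))
  group[1] <- grp
  for (i in seq_len(nrow(op))[-1]) {
    adjoining <- op$low_valley_idx[i] == op$high_valley_idx[i - 1L]
    v <- op$low_valley_value[i]
    not_separated <- v > separation_factor * min(op$height[i], op$height[i - 1L])
    if (adjoining && not_separated) group[i] <- group[i - 1L] else {
      grp <- grp + 1L; group[i] <- grp
    }
  }
  purrr::map_dfr(split(seq_len(nrow(op)), group), function(ix) {
    m <- op[ix, ]
    tibble(
      start_bp = m$low_valley_bp[1],
      end_bp = m$high_valley_bp[nrow(m)],
      n_peaks = nrow(m),
      max_height = max(m$height),
      apex_bp = m$apex_bp[which.max(m$height)],
      members = list(m)
    )
  })
}

#' Optimal extent/probability parameters for a peak
#'
#' Over the peak's loci and the percentile grid of the percentile-extent
#' matrix, each pair (Extent = matrix value, Pr = 1 - percentile/100) is a
#' candidate segment-length threshold with its exceedance probability; the
#' pair maximising Extent x Pr gives `extent_min` and `p_max` (ties resolve
#' toward the larger extent).  The expected haplotype frequency is
#' `freq_hap_exp = sqrt(p_max)`: if a single haplotype explains the peak's
#' homozygosity beyond `extent_min`, homozygote carriers arise at the
#' squared haplotype frequency.  `freq_hap_max` is the largest
#' founder-haplotype frequency among segments intersecting the peak whose
#' length exceeds `extent_min` (0 when none qualifies).
#'
#' @param peak One row of a peak tibble.
#' @param pemat An `hz_pemat` for the peak's population.
#' @param segments Annotated segments with `founder_hap_freq` and length in
#'   the matrix's units (`length_bp` or `length_cm`).
#' @return A one-row tibble: `extent_min`, `p_max`, `freq_hap_exp`,
#'   `freq_hap_max`.
#' @export
peak_haplotype_params <- function(peak, pemat, segments = NULL) {
  sel <- pemat$loci$position_bp >= peak$low_valley_bp &
    pemat$loci$position_bp <= peak$high_valley_bp
  block <- pemat$values[sel, , drop = FALSE]
  pr <- 1 - pemat$percentiles / 100
  prod_mat <- sweep(block, 2, pr, `*`)
  best <- max(prod_mat, na.rm = TRUE)
  cand <- which(!is.na(prod_mat) & prod_mat >= best - 1e-12, arr.ind = TRUE)
  ext <- block[cand]
  pick <- which.max(ext)
  extent_min <- ext[pick]
  p_max <- pr[cand[pick, 2]]
  freq_hap_max <- 0
  if (!is.null(segments)) {
    len_col <- if (pemat$units == "cm") "length_cm" else "length_bp"
    hit <- segments$chromosome == pemat$chromosome &
      segments$end_bp >= peak$low_valley_bp &
      segments$start_bp <= peak$high_valley_bp &
      segments[[len_col]] > extent_min
    if ("population" %in% names(segments)) {
      hit <- hit & segments$population == pemat$population
    }
    if (any(hit)) {
      v <- segments$founder_hap_freq[hit]
      v <- v[!is.na(v)]
      if (length(v)) freq_hap_max <- max(v)
    }
  }
  tibble(extent_min = extent_min, p_max = p_max,
         freq_hap_exp = sqrt(p_max), freq_hap_max = freq_hap_max)
}

#' Maximum ext_AUC rank of each population within a peak
#'
#' For each population's rank track, the maximum per-locus rank between the
#' peak's valleys, quantifying how outstanding the peak's span is in every
#' population (not just the one it was detected in).
#'
#' @param peak One peak row.
#' @param tracks A named list of rank tracks from [ext_auc_rank()] (one per
#'   population) or a single combined tibble.
#' @return A named numeric vector of maximum ranks.
#' @export
cross_population_rank <- function(peak, tracks) {
  if (is.data.frame(tracks)) tracks <- split(tracks, tracks$population)
  vapply(tracks, function(tr) {
    sel <- tr$position_bp >= peak$low_valley_bp &
      tr$position_bp <= peak$high_valley_bp
    if (!any(sel)) return(NA_real_)
    max(tr$rank[sel])
  }, numeric(1))
}

#' Detect candidate fixed areas (RCL_0)
#'
#' Maximal runs of consecutive loci whose 0th-percentile extent is
#' positive: stretches covered by a homozygous segment in every sample of
#' the population, i.e. areas where one haplotype is at or near fixation.
#' Candidate fixed areas are the runs whose SNP count and extent both
#' exceed the first quartiles computed over all supplied populations' runs.
#'
#' @param pemats A list of `hz_pemat` objects (one per population), or one
#'   object.
#' @param quartile_scope `"pooled"` (default): the first-quartile thresholds
#'   for candidate areas are computed over all populations' runs together;
#'   `"per_population"`: within each population separately.
#' @return A tibble of runs: `population`, `chromosome`, `start_idx`,
#'   `end_idx`, `start_bp`, `end_bp`, `snp_count`, `extent` (max
#'   0th-percentile value in the run, matrix units), `extent_bp`,
#'   `candidate` flag.
#' @export
detect_fixed_areas <- function(pemats,
                               quartile_scope = c("pooled", "per_population")) {
  quartile_scope <- match.arg(quartile_scope)
  if (inherits(pemats, "hz_pemat")) pemats <- list(pemats)
  runs <- purrr::map_dfr(pemats, function(pm) {
    v0 <- pm$values[, 1]
    pos <- !is.na(v0) & v0 > 0
    if (!any(pos)) return(NULL)
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    purrr::map_dfr(which(keep), function(k) {
      s <- starts[k]; e <- ends[k]
      tibble(
        population = pm$population,
        chromosome = pm$chromosome,
        start_idx = s, end_idx = e,
        start_bp = pm$loci$position_bp[s],
        end_bp = pm$loci$position_bp[e],
        snp_count = e - s + 1L,
        extent = max(v0[s:e]),
        extent_bp = pm$loci$position_bp[e] - pm$loci$position_bp[s] + 1L
      )
    })
  })
  if (nrow(runs) == 0) {
    return(tibble(
      population = character(), chromosome = character(), start_idx = integer(),
      end_idx = integer(), start_bp = integer(), end_bp = integer(),
      snp_count = integer(), extent = numeric(), extent_bp = integer(),
      candidate = logical()
    ))
  }
  if (quartile_scope == "pooled") {
    q1_snp <- quantile(runs$snp_count, 0.25, type = 7, names = FALSE)
    q1_ext <- quantile(runs$extent, 0.25, type = 7, names = FALSE)
    runs$candidate <- runs$snp_count > q1_snp & runs$extent > q1_ext
  } else {
    runs <- runs |>
      group_by(.data$population) |>
      mutate(candidate = .data$snp_count >
               quantile(.data$snp_count, 0.25, type = 7, names = FALSE) &
               .data$extent >
               quantile(.data$extent, 0.25, type = 7, names = FALSE)) |>
      ungroup()
  }
  runs
}

#' Recombination rate across a peak and its genome-wide percentile
#'
#' The rate window is centred on the midpoint of the loci whose ext_AUC
#' values fall in the peak's upper quartile, with width a configurable
#' fraction of the peak width; the rate is the genetic-map distance across
#' the window divided by its physical length.  The percentile places that
#' rate within reference rates computed for same-sized windows tiled along
#' the chromosome (bin width snapped to a standard grid), since the
#' rate distribution depends on window size.
#'
#' @param peak One peak row.
#' @param track The population's ext_AUC track for the chromosome.
#' @param genetic_map Tibble `chromosome`, `position_bp`, `cm` covering the
#'   window.
#' @param window_fraction Window width as a fraction of peak width
#'   (default 0.5).
#' @return A one-row tibble: `recomb_rate` (cM/Mb), `recomb_rate_percentile`,
#'   `window_start_bp`, `window_end_bp`, `bin_bp`.
#' @export
peak_recombination <- function(peak, track, genetic_map,
                               window_fraction = 0.5) {
  sel <- track$position_bp >= peak$low_valley_bp &
    track$position_bp <= peak$high_valley_bp
  vals <- track$ext_auc[sel]
  pos <- track$position_bp[sel]
  top <- pos[vals >= quantile(vals, 0.75, type = 7, names = FALSE)]
  centre <- (min(top) + max(top)) / 2
  width <- (peak$high_valley_bp - peak$low_valley_bp) * window_fraction
  w_start <- centre - width / 2
  w_end <- centre + width / 2
  map <- genetic_map[genetic_map$chromosome == peak$chromosome, ]
  if (nrow(map) < 2 || w_start < min(map$position_bp) ||
      w_end > max(map$position_bp)) {
    abort("genetic map does not cover the peak window")
  }
  cm_at <- function(p) approx(map$position_bp, map$cm, xout = p)$y
  rate <- (cm_at(w_end) - cm_at(w_start)) / ((w_end - w_start) / 1e6)
  bins <- recombination_bin_grid()
  bin <- bins[which.min(abs(bins - width))]
  ref <- reference_window_rates(map, bin)
  pct <- if (length(ref) == 0) NA_real_ else ecdf(ref)(rate)
  tibble(recomb_rate = rate, recomb_rate_percentile = pct,
         window_start_bp = w_start, window_end_bp = w_end, bin_bp = bin)
}

#' Standard window-size grid for recombination-rate references
#'
#' @return Bin widths in bp: 5 kb; 10-100 kb by 10; 200-500 kb by 100;
#'   750 kb; 1 Mb; 5 Mb; 10 Mb.
#' @export
recombination_bin_grid <- function() {
  c(5e3, seq(1e4, 1e5, by = 1e4), seq(2e5, 5e5, by = 1e5), 7.5e5, 1e6, 5e6, 1e7)
}

# Rates for non-overlapping windows of width `bin` tiled over the map span.
reference_window_rates <- function(map, bin) {
  lo <- min(map$position_bp); hi <- max(map$position_bp)
  starts <- seq(lo, hi - bin, by = bin)
  if (length(starts) == 0) return(numeric())
  cm <- approx(map$position_bp, map$cm, xout = c(starts, starts + bin))$y
  n <- length(starts)
  (cm[(n + 1):(2 * n)] - cm[seq_len(n)]) / (bin / 1e6)
}
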