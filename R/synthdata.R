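#' Configuration for the synthetic genotype-panel generator
#'
#' The generator emulates a block-haplotype (windowed founder-pool)
#' population: the chromosome is cut into contiguous windows, each window
#' carries a small pool of founder haplotypes with fixed frequencies, and
#' every individual draws two founders per window.  Identical draws make
#' the window homozygous, so contiguous homozygosity arises whenever
#' neighbouring windows are simultaneously homozygous; genotyping error
#' (homozygote-to-heterozygote flips) and missingness are layered on top.
#' Planted features force known truth into the panel: an autozygous tract
#' copies one private haplotype onto both chromosomes of one sample; an
#' extended haplotype forces one founder to an exact target frequency; a
#' fixed region makes one founder universal in one population.
#'
#' @param n_samples Named integer vector: samples per population.
#' @param n_loci Number of loci.
#' @param n_windows Number of founder windows.
#' @param founders_per_window Founder haplotypes per window.
#' @param founder_freqs Frequency vector (length `founders_per_window`,
#'   summing to 1) shared by all windows.  The default (`NULL`) draws a
#'   geometric frequency profile per window with a window-specific skew in
#'   `skew_range`, so background homozygosity varies along the chromosome
#'   the way local LD strength does.
#' @param skew_range Range of the per-window geometric skew parameter used
#'   when `founder_freqs` is `NULL`.
#' @param base_spacing_bp Mean inter-SNP spacing.
#' @param big_gap_prob,big_gap_bp Heavy-tail gap model: each gap is
#'   replaced by `big_gap_bp` with this probability.
#' @param het_error_rate Probability a homozygous genotype is mis-called
#'   heterozygous.
#' @param missing_rate Probability a genotype is a no-call.
#' @param autozygous_tracts List of `list(sample_id, start_locus,
#'   end_locus)`.
#' @param extended_haplotypes List of `list(start_locus, end_locus,
#'   frequency)` with `frequency` a named vector per population.
#' @param fixed_regions List of `list(start_locus, end_locus, population)`.
#' @param fixed_wall_width Number of loci flanking each planted fixed
#'   region at which every sample of the target population is made
#'   heterozygous (a "diversity wall", emulating the restored diversity at
#'   a swept region's edge).  It gives the planted boundary a sharp,
#'   well-defined truth coordinate; 0 disables (default 8).
#' @param chromosome Chromosome label.
#' @param arm_boundary_locus Locus index at which the q arm starts.
#' @param seed Integer seed; all draws are reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = c(popA = 50, popB = 50),
                       n_loci = 5000,
                       n_windows = 25,
                       founders_per_window = 8,
                       founder_freqs = NULL,
                       skew_range = c(0.1, 0.35),
                       base_spacing_bp = 1000,
                       big_gap_prob = 0.002,
                       big_gap_bp = 2e5,
                       het_error_rate = 0.002,
                       missing_rate = 0.002,
                       autozygous_tracts = list(),
                       extended_haplotypes = list(),
                       fixed_regions = list(),
                       fixed_wall_width = 8,
                       chromosome = "1",
                       arm_boundary_locus = NULL,
                       seed = 1L) {
  if (is.null(names(n_samples))) {
    names(n_samples) <- paste0("pop", seq_along(n_samples))
  }
  if (!is.null(founder_freqs)) {
    if (abs(sum(founder_freqs) - 1) > 1e-8) abort("founder_freqs must sum to 1")
    if (length(founder_freqs) != founders_per_window) {
      abort("founder_freqs length must equal founders_per_window")
    }
  }
  stopifnot(het_error_rate >= 0, het_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  for (f in c(autozygous_tracts, extended_haplotypes, fixed_regions)) {
    if (f$start_locus < 1 || f$end_locus > n_loci || f$start_locus > f$end_locus) {
      abort("planted feature interval outside [1, n_loci]")
    }
  }
  for (f in extended_haplotypes) {
    fr <- unlist(f$frequency)
    if (any(fr < 0 | fr > 1)) abort("infeasible planted frequency")
  }
  if (is.null(arm_boundary_locus)) arm_boundary_locus <- ceiling(n_loci / 2)
  structure(list(
    n_samples = n_samples, n_loci = n_loci, n_windows = n_windows,
    founders_per_window = founders_per_window, founder_freqs = founder_freqs,
    skew_range = skew_range,
    base_spacing_bp = base_spacing_bp, big_gap_prob = big_gap_prob,
    big_gap_bp = big_gap_bp, het_error_rate = het_error_rate,
    missing_rate = missing_rate, autozygous_tracts = autozygous_tracts,
    extended_haplotypes = extended_haplotypes, fixed_regions = fixed_regions,
    fixed_wall_width = fixed_wall_width,
    chromosome = chromosome, arm_boundary_locus = arm_boundary_locus,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_sim_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  )
  set.seed(seed)
  force(code)
}

window_bounds <- function(n_loci, n_windows) {
  ends <- round(seq_len(n_windows) / n_windows * n_loci)
  starts <- c(1L, head(ends, -1) + 1L)
  tibble(window = seq_len(n_windows), start = as.integer(starts),
         end = as.integer(ends))
}

#' Simulate a genotype panel with planted truth
#'
#' Draws founder pools and haplotypes per [sim_config()], applies planted
#' features, layers genotyping error and missingness, and returns the
#' genotype matrix, the error-free phased haplotype panel, and a truth
#' table of realized feature coordinates and frequencies.  Planted feature
#' intervals are realized on whole founder windows (the windows the
#' requested interval overlaps); the truth table records the realized
#' coordinates.  Fully deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list: `gm` ([genotype_matrix()]), `panel` ([phased_panel()]),
#'   `truth` (list of tibbles `tracts`, `extended`, `fixed`), `windows`.
#' @export
simulate_panel <- function(cfg) {
  with_sim_seed(cfg$seed, {
    n_pop <- cfg$n_samples
    pops <- names(n_pop)
    n_tot <- sum(n_pop)
    sample_ids <- unlist(lapply(pops, function(p) {
      sprintf("%s_s%03d", p, seq_len(n_pop[[p]]))
    }))
    sample_pop <- rep(pops, times = n_pop)
    # positions
    gaps <- round(cfg$base_spacing_bp * (0.5 + runif(cfg$n_loci - 1)))
    big <- runif(cfg$n_loci - 1) < cfg$big_gap_prob
    gaps[big] <- cfg$big_gap_bp
    positions <- cumsum(c(1, gaps))
    wb <- window_bounds(cfg$n_loci, cfg$n_windows)
    k <- cfg$founders_per_window
    # founder pools: k x window-length 0/1 allele matrices
    pools <- lapply(seq_len(cfg$n_windows), function(w) {
      len <- wb$end[w] - wb$start[w] + 1L
      matrix(rbinom(k * len, 1, 0.5), nrow = k)
    })
    # per-window founder frequencies, shared by the populations: either the
    # configured fixed profile or a geometric profile with per-window skew
    base_freqs <- lapply(seq_len(cfg$n_windows), function(w) {
      if (!is.null(cfg$founder_freqs)) return(cfg$founder_freqs)
      lambda <- runif(1, cfg$skew_range[1], cfg$skew_range[2])
      f <- exp(-lambda * (seq_len(k) - 1))
      f / sum(f)
    })
    freqs <- lapply(seq_len(cfg$n_windows), function(w) {
      sapply(pops, function(p) base_freqs[[w]], simplify = FALSE)
    })
    overlapping_windows <- function(f) {
      which(wb$end >= f$start_locus & wb$start <= f$end_locus)
    }
    hap_pop <- rep(sample_pop, each = 2)
    # preassigned founders (NA = free draw): windows x populations
    preassign <- lapply(seq_len(cfg$n_windows), function(w) {
      sapply(pops, function(p) rep(NA_integer_, sum(hap_pop == p)),
             simplify = FALSE)
    })
    # extended haplotypes: founder 1 forced to an exact carrier count, the
    # same carrier chromosomes across all of the feature's windows
    ext_truth <- purrr::map_dfr(cfg$extended_haplotypes, function(f) {
      ws <- overlapping_windows(f)
      for (p in names(f$frequency)) {
        nh <- 2 * n_pop[[p]]
        cnt <- as.integer(round(nh * f$frequency[[p]]))
        carrier <- sample.int(nh, cnt)
        for (w in ws) preassign[[w]][[p]][carrier] <<- 1L
      }
      tibble(
        start_idx = wb$start[min(ws)], end_idx = wb$end[max(ws)],
        population = names(f$frequency),
        target_freq = unname(unlist(f$frequency)),
        realized_freq = unname(vapply(names(f$frequency), function(p) {
          round(2 * n_pop[[p]] * f$frequency[[p]]) / (2 * n_pop[[p]])
        }, numeric(1)))
      )
    })
    fix_truth <- purrr::map_dfr(cfg$fixed_regions, function(f) {
      ws <- overlapping_windows(f)
      p <- f$population
      for (w in ws) preassign[[w]][[p]][] <<- 1L
      tibble(
        population = p,
        start_idx = wb$start[min(ws)], end_idx = wb$end[max(ws)]
      )
    })
    # founder index draws: 2 haplotypes per sample per window
    H <- matrix(0L, nrow = 2 * n_tot, ncol = cfg$n_loci)
    for (w in seq_len(cfg$n_windows)) {
      cols <- wb$start[w]:wb$end[w]
      for (p in pops) {
        rows <- which(hap_pop == p)
        founder <- preassign[[w]][[p]]
        free <- is.na(founder)
        if (any(free)) {
          if (all(free)) {
            founder[free] <- sample.int(k, sum(free), replace = TRUE,
                                        prob = freqs[[w]][[p]])
          } else {
            # founder 1 is taken by forced carriers; draw the rest from the
            # remaining pool so the forced frequency is exact
            rest_freq <- freqs[[w]][[p]][-1]
            founder[free] <- 1L + sample.int(k - 1L, sum(free), replace = TRUE,
                                             prob = rest_freq / sum(rest_freq))
          }
        }
        H[rows, cols] <- pools[[w]][founder, , drop = FALSE]
      }
    }
    # diversity walls flanking fixed regions: the target population is made
    # heterozygous there, giving the planted boundary a sharp coordinate
    if (cfg$fixed_wall_width > 0) {
      for (f in cfg$fixed_regions) {
        ws <- overlapping_windows(f)
        lo <- wb$start[min(ws)]; hi <- wb$end[max(ws)]
        wall <- c(
          if (lo > 1) seq.int(max(1L, lo - cfg$fixed_wall_width), lo - 1L),
          if (hi < cfg$n_loci) seq.int(hi + 1L,
                                       min(cfg$n_loci, hi + cfg$fixed_wall_width))
        )
        rows <- which(hap_pop == f$population)
        H[rows[seq(1, length(rows), by = 2)], wall] <- 0L
        H[rows[seq(2, length(rows), by = 2)], wall] <- 1L
      }
    }
    # autozygous tracts: private haplotype copied onto both chromosomes
    tract_truth <- purrr::map_dfr(cfg$autozygous_tracts, function(f) {
      si <- match(f$sample_id, sample_ids)
      if (is.na(si)) abort(sprintf("unknown sample id %s", f$sample_id))
      span <- f$start_locus:f$end_locus
      private <- rbinom(length(span), 1, 0.5)
      H[2 * si - 1L, span] <<- private
      H[2 * si, span] <<- private
      tibble(
        sample_id = f$sample_id,
        start_idx = f$start_locus, end_idx = f$end_locus,
        start_bp = positions[f$start_locus], end_bp = positions[f$end_locus]
      )
    })
    calls <- H[seq(1, 2 * n_tot, by = 2), , drop = FALSE] +
      H[seq(2, 2 * n_tot, by = 2), , drop = FALSE]
    # genotyping error then missingness
    hom <- calls != 1L
    flip <- hom & matrix(runif(length(calls)) < cfg$het_error_rate, nrow(calls))
    calls[flip] <- 1L
    mis <- matrix(runif(length(calls)) < cfg$missing_rate, nrow(calls))
    calls[mis] <- CALL_MISSING
    loci <- tibble(
      id = sprintf("snp%05d", seq_len(cfg$n_loci)),
      chromosome = cfg$chromosome,
      position_bp = as.integer(positions),
      allele_a = "A", allele_b = "B",
      arm = ifelse(seq_len(cfg$n_loci) < cfg$arm_boundary_locus, "p", "q")
    )
    samples <- tibble(id = sample_ids, population = sample_pop, sex = "female")
    gm <- genotype_matrix(calls, loci, samples)
    panel <- phased_panel(H, rep(sample_ids, each = 2), rep(sample_pop, each = 2))
    if (nrow(ext_truth) > 0) {
      ext_truth$start_bp <- positions[ext_truth$start_idx]
      ext_truth$end_bp <- positions[ext_truth$end_idx]
    }
    if (nrow(fix_truth) > 0) {
      fix_truth$start_bp <- positions[fix_truth$start_idx]
      fix_truth$end_bp <- positions[fix_truth$end_idx]
    }
    list(
      gm = gm, panel = panel,
      truth = list(tracts = tract_truth, extended = ext_truth,
                   fixed = fix_truth),
      windows = wb
    )
  })
}

#' Simulate two groups with a segment-length shift in a target window range
#'
#' Both groups share the generator of [simulate_panel()], but within the
#' target windows group B's founder frequencies are sharpened
#' (`p^shift`, renormalised) so identical founder draws -- and hence
#' longer runs of contiguous homozygosity -- become more (shift > 1) or
#' less (shift < 1) likely.  The truth records the target window span.
#'
#' @param cfg A [sim_config()] with exactly two populations.
#' @param shift Sharpening exponent (> 0).
#' @param window_range Integer vector of window indices to modify.
#' @return As [simulate_panel()], plus `truth$shift_window` with the
#'   realized coordinates.
#' @export
simulate_two_group_shift <- function(cfg, shift = 3, window_range = NULL) {
  stopifnot(shift > 0, length(cfg$n_samples) == 2)
  if (is.null(window_range)) {
    window_range <- ceiling(cfg$n_windows / 2)
  }
  wb <- window_bounds(cfg$n_loci, cfg$n_windows)
  pop_b <- names(cfg$n_samples)[2]
  # implement through a forced-frequency extended haplotype in group B:
  # sharpen by boosting the top founder's frequency
  p <- cfg$founder_freqs
  if (is.null(p)) {
    p <- exp(-mean(cfg$skew_range) * (seq_len(cfg$founders_per_window) - 1))
    p <- p / sum(p)
  }
  p_sharp <- p^shift / sum(p^shift)
  cfg$extended_haplotypes <- c(cfg$extended_haplotypes, list(list(
    start_locus = wb$start[min(window_range)],
    end_locus = wb$end[max(window_range)],
    frequency = setNames(list(p_sharp[1]), pop_b)
  )))
  out <- simulate_panel(cfg)
  out$truth$shift_window <- tibble(
    start_idx = wb$start[min(window_range)],
    end_idx = wb$end[max(window_range)],
    start_bp = out$gm$loci$position_bp[wb$start[min(window_range)]],
    end_bp = out$gm$loci$position_bp[wb$end[max(window_range)]],
    shift = shift
  )
  out
}

#' Simulate a genetic map with piecewise-constant recombination rate
#'
#' @param positions Base-pair positions (e.g. `gm$loci$position_bp`).
#' @param chromosome Chromosome label.
#' @param base_rate Background rate in cM/Mb.
#' @param hotspots Optional tibble `start_bp`, `end_bp`, `rate` overriding
#'   the base rate.
#' @param arm_boundary_bp Position at which the q arm starts (default:
#'   midpoint).
#' @return A list: `map` (tibble `chromosome`, `position_bp`, `cm`,
#'   monotone non-decreasing) and `arm_rates` (length-weighted mean rate
#'   per arm, consistent with the map).
#' @export
simulate_genetic_map <- function(positions, chromosome = "1", base_rate = 1,
                                 hotspots = NULL, arm_boundary_bp = NULL) {
  positions <- sort(positions)
  if (is.null(arm_boundary_bp)) {
    arm_boundary_bp <- (min(positions) + max(positions)) / 2
  }
  rate_at <- function(p) {
    r <- rep(base_rate, length(p))
    if (!is.null(hotspots)) {
      for (i in seq_len(nrow(hotspots))) {
        r[p >= hotspots$start_bp[i] & p < hotspots$end_bp[i]] <- hotspots$rate[i]
      }
    }
    r
  }
  # integrate the piecewise-constant rate along the position grid
  brk <- sort(unique(c(positions,
                       if (!is.null(hotspots)) c(hotspots$start_bp, hotspots$end_bp))))
  brk <- brk[brk >= min(positions) & brk <= max(positions)]
  seg_cm <- diff(brk) / 1e6 * rate_at(brk[-length(brk)])
  cm_brk <- c(0, cumsum(seg_cm))
  cm <- approx(brk, cm_brk, xout = positions)$y
  map <- tibble(chromosome = chromosome, position_bp = as.integer(positions),
                cm = cm)
  arm_mean <- function(lo, hi) {
    pts <- brk[brk >= lo & brk <= hi]
    pts <- sort(unique(c(lo, pts, hi)))
    sum(diff(pts) * rate_at(pts[-length(pts)])) / (hi - lo)
  }
  arm_rates <- tibble(
    chromosome = chromosome,
    arm = c("p", "q"),
    start_bp = as.integer(c(min(positions), ceiling(arm_boundary_bp))),
    end_bp = as.integer(c(ceiling(arm_boundary_bp) - 1, max(positions))),
    cm_per_mb = c(arm_mean(min(positions), ceiling(arm_boundary_bp) - 1),
                  arm_mean(ceiling(arm_boundary_bp), max(positions)))
  )
  list(map = map, arm_rates = arm_rates)
}
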