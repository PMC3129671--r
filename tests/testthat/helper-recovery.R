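# Planted-truth recovery experiments used by the acceptance tests.  Each
# experiment simulates a panel with one planted feature, runs the standard
# detection/annotation/extent/peak pipeline, and measures how well the
# feature is recovered.  The study conditions (panel sizes, feature sizes,
# error rates) are fixed here.

# Planted autozygous tract (3.5 Mb in a 5 Mb chromosome, 0.5% het error):
# returns the covering segment's tract coverage, MAD score and
# founder-haplotype frequency.
recover_tract <- function(seed) {
  cfg <- sim_config(
    n_samples = c(popA = 40), n_loci = 5000, n_windows = 100,
    het_error_rate = 0.005,
    autozygous_tracts = list(list(sample_id = "popA_s001",
                                  start_locus = 751, end_locus = 4250)),
    seed = seed
  )
  sim <- simulate_panel(cfg)
  segs <- annotate_segments(detect_segments(sim$gm), sim$gm,
                            panel = sim$panel)
  t <- sim$truth$tracts
  hit <- segs[segs$sample_id == t$sample_id &
                segs$start_bp <= t$end_bp & segs$end_bp >= t$start_bp, ]
  cov <- (pmin(hit$end_bp, t$end_bp) - pmax(hit$start_bp, t$start_bp) + 1) /
    (t$end_bp - t$start_bp + 1)
  best <- which.max(cov)
  bg <- segs[segs$sample_id != t$sample_id & !is.na(segs$mad_score), ]
  list(coverage = cov[best], mad_score = hit$mad_score[best],
       founder_hap_freq = hit$founder_hap_freq[best],
       background_call_rate = mean(bg$putative_autozygous &
                                     bg$founder_hap_freq == 0))
}

# Planted extended haplotype at frequency f: returns whether the peak
# covering the planted midpoint is an outlier and the error of its
# freq_hap_max against the realized planted frequency target.
recover_extended <- function(seed, f) {
  if (f >= 0.5) {
    n_samp <- c(popA = 30); n_loci <- 5000; n_win <- 100; feat <- c(2001, 2800)
  } else {
    n_samp <- c(popA = 100); n_loci <- 6000; n_win <- 120; feat <- c(3001, 3550)
  }
  cfg <- sim_config(
    n_samples = n_samp, n_loci = n_loci, n_windows = n_win,
    extended_haplotypes = list(list(start_locus = feat[1], end_locus = feat[2],
                                    frequency = c(popA = f))),
    seed = seed
  )
  sim <- simulate_panel(cfg)
  gmap <- simulate_genetic_map(sim$gm$loci$position_bp)
  segs <- annotate_segments(detect_segments(sim$gm), sim$gm, panel = sim$panel)
  segs$length_cm <- segments_cm(segs, gmap$arm_rates)
  islm <- mask_islm_autozygous(
    build_islm(segs, sim$gm, units = "cm", arm_rates = gmap$arm_rates)
  )
  pm <- pe_mat(islm, "popA")
  tr <- ext_auc(islm, "popA")
  pk <- flag_outlier_peaks(merge_peaks(detect_peaks(
    smooth_track(tr$ext_auc, tr$position_bp)
  )))
  e <- sim$truth$extended
  mid <- (e$start_bp + e$end_bp) / 2
  hit <- pk[pk$low_valley_bp <= mid & pk$high_valley_bp >= mid, ]
  if (nrow(hit) == 0) return(list(outlier = FALSE, freq_error = NA_real_))
  hit$chromosome <- "1"
  hp <- peak_haplotype_params(hit[1, ], pm, segments = segs)
  list(outlier = isTRUE(hit$outlier[1]),
       freq_error = abs(hp$freq_hap_max - f))
}

# Planted fixed region on a clean two-population panel: returns the
# boundary error (in SNPs) of the best-overlapping zero-percentile run.
recover_fixed <- function(seed) {
  cfg <- sim_config(
    n_samples = c(popA = 30, popB = 30), n_loci = 2000, n_windows = 40,
    het_error_rate = 0, missing_rate = 0, big_gap_prob = 0,
    fixed_regions = list(list(start_locus = 1201, end_locus = 1600,
                              population = "popA")),
    seed = seed
  )
  sim <- simulate_panel(cfg)
  gmap <- simulate_genetic_map(sim$gm$loci$position_bp)
  segs <- annotate_segments(detect_segments(sim$gm), sim$gm, panel = sim$panel)
  islm <- mask_islm_autozygous(
    build_islm(segs, sim$gm, units = "cm", arm_rates = gmap$arm_rates)
  )
  runs <- detect_fixed_areas(pe_mat(islm, "popA"))
  f <- sim$truth$fixed
  ov <- runs[runs$end_idx >= f$start_idx & runs$start_idx <= f$end_idx, ]
  if (nrow(ov) == 0) return(NA_integer_)
  ovl <- pmin(ov$end_idx, f$end_idx) - pmax(ov$start_idx, f$start_idx) + 1
  best <- which.max(ovl)
  max(abs(ov$start_idx[best] - f$start_idx), abs(ov$end_idx[best] - f$end_idx))
}
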