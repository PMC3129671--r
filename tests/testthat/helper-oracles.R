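# Independent brute-force oracles and fixture builders shared by the tests.
# Each oracle is deliberately written as plain enumeration, not by reusing
# the package's own code paths.

# Build a one-sample genotype matrix from a call vector.
make_gm1 <- function(calls, positions = NULL, chromosome = "1",
                     population = "p", sample_id = "s1") {
  n <- length(calls)
  if (is.null(positions)) positions <- seq_len(n) * 1000L
  genotype_matrix(
    matrix(as.integer(calls), nrow = 1),
    tibble::tibble(id = paste0("L", seq_len(n)), chromosome = chromosome,
                   position_bp = as.integer(positions),
                   allele_a = "A", allele_b = "B"),
    tibble::tibble(id = sample_id, population = population)
  )
}

# Multi-sample genotype matrix from a calls matrix (samples x loci).
make_gm <- function(calls, positions = NULL, chromosome = "1",
                    populations = NULL) {
  n <- ncol(calls)
  if (is.null(positions)) positions <- seq_len(n) * 1000L
  if (is.null(populations)) populations <- rep("p", nrow(calls))
  genotype_matrix(
    calls,
    tibble::tibble(id = paste0("L", seq_len(n)), chromosome = chromosome,
                   position_bp = as.integer(positions),
                   allele_a = "A", allele_b = "B"),
    tibble::tibble(id = paste0("s", seq_len(nrow(calls))),
                   population = populations)
  )
}

# Detection params that disable gap splitting and the scan-ahead screen, so
# segment extraction is governed by the het-proportion rule alone.
het_only_params <- function(max_het = 0.01) {
  detection_params(
    gap_width_join_thresholds = permissive_gap_thresholds(),
    gap_width_scan_thresholds = permissive_gap_thresholds(),
    max_het_proportion = max_het,
    scan_ahead_het_threshold = 1,
    max_dense_het = 1
  )
}

# Exhaustive left-greedy maximal-extension enumerator: from each start, try
# every homozygous end and keep the farthest whose span satisfies the het
# rule; emitted segments need >= 2 homozygous calls.
oracle_segments <- function(calls, max_het = 0.01) {
  hom <- calls == 0 | calls == 2
  het <- calls == 1
  segs <- NULL
  i <- 1
  hom_idx_all <- which(hom)
  repeat {
    hom_idx <- hom_idx_all[hom_idx_all >= i]
    if (length(hom_idx) == 0) break
    s <- hom_idx[1]
    best <- s
    for (j in hom_idx) {
      span <- s:j
      h <- sum(het[span])
      cc <- sum(calls[span] != 3)
      if (h / cc <= max_het) best <- j
    }
    segs <- rbind(segs, c(s, best))
    i <- best + 1
  }
  if (is.null(segs)) return(matrix(integer(), ncol = 2))
  keep <- vapply(seq_len(nrow(segs)), function(k) {
    sum(calls[segs[k, 1]:segs[k, 2]] %in% c(0, 2)) >= 2
  }, logical(1))
  segs[keep, , drop = FALSE]
}

# Random call vector with given het/missing rates.
random_calls <- function(n, p_het = 0.03, p_mis = 0.03) {
  p_hom <- (1 - p_het - p_mis) / 2
  sample(c(0L, 2L, 1L, 3L), n, replace = TRUE,
         prob = c(p_hom, p_hom, p_het, p_mis))
}

# Full enumeration of the conditional heterozygote-count distribution for
# the HWE exact test (probabilities via exact rational-free accumulation).
oracle_hwe <- function(a, b, cc) {
  n <- a + b + cc
  n_rare <- 2 * min(a, cc) + b
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  wt <- vapply(hets, function(h) {
    rare_hom <- (n_rare - h) / 2
    common_hom <- n - h - rare_hom
    exp(h * log(2) + lfactorial(n)
        - lfactorial(rare_hom) - lfactorial(h) - lfactorial(common_hom))
  }, numeric(1))
  p <- wt / sum(wt)
  p_obs <- p[hets == b]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

# Sort-based type-7 quantile, written from the definition.
oracle_quantile7 <- function(x, prob) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * prob + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Brute-force two-sample CvM omega2 from the definition.
oracle_omega2 <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  tot <- 0
  for (x in xs) {
    fa <- mean(a <= x)
    fb <- mean(b <= x)
    tot <- tot + (fa - fb)^2
  }
  tot
}

# Nested-ANOVA (three-level sums-of-squares) route to the two-population
# theta estimator: expand genotypes to per-individual allele indicators and
# apply the method-of-moments decomposition.
oracle_theta_anova <- function(counts_a, counts_b) {
  expand <- function(cnt) {
    # rows: individuals; cols: two allele indicators (1 = ref allele)
    rbind(
      matrix(1, nrow = cnt[1], ncol = 2),
      if (cnt[2] > 0) matrix(rep(c(1, 0), cnt[2]), ncol = 2, byrow = TRUE),
      matrix(0, nrow = cnt[3], ncol = 2)
    )
  }
  pops <- list(expand(counts_a), expand(counts_b))
  n_i <- vapply(pops, nrow, numeric(1))
  r <- 2
  y_bar <- sum(vapply(pops, sum, numeric(1))) / (2 * sum(n_i))
  p_i <- vapply(pops, function(m) mean(m), numeric(1))
  ind_means <- lapply(pops, rowMeans)
  # sums of squares: populations / individuals-within / alleles-within
  ss_p <- sum(2 * n_i * (p_i - y_bar)^2)
  ss_i <- sum(unlist(lapply(seq_along(pops), function(k) {
    2 * (ind_means[[k]] - p_i[k])^2
  })))
  ss_g <- sum(unlist(lapply(seq_along(pops), function(k) {
    (pops[[k]] - ind_means[[k]])^2
  })))
  ms_p <- ss_p / (r - 1)
  ms_i <- ss_i / (sum(n_i) - r)
  ms_g <- ss_g / sum(n_i)
  n_c <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  s2_g <- ms_g
  s2_i <- (ms_i - ms_g) / 2
  s2_p <- (ms_p - ms_i) / (2 * n_c)
  s2_p / (s2_p + s2_i + s2_g)
}

# Small simulated panel reused across extent/peak tests (cached per session).
fixture_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_samples = c(popA = 25, popB = 25), n_loci = 2500, n_windows = 12,
        extended_haplotypes = list(list(start_locus = 1200, end_locus = 1700,
                                        frequency = c(popA = 0.6))),
        seed = 20260915
      )
      sim <- simulate_panel(cfg)
      segs <- detect_segments(sim$gm)
      segs <- annotate_segments(segs, sim$gm, panel = sim$panel)
      gmap <- simulate_genetic_map(sim$gm$loci$position_bp)
      segs$length_cm <- vapply(seq_len(nrow(segs)), function(i) {
        interval_cm(segs$chromosome[i], segs$start_bp[i], segs$end_bp[i],
                    gmap$arm_rates)
      }, numeric(1))
      islm <- build_islm(segs, sim$gm, units = "cm",
                         arm_rates = gmap$arm_rates)
      islm <- mask_islm_autozygous(islm)
      cache <<- list(sim = sim, segs = segs, islm = islm, gmap = gmap)
    }
    cache
  }
})
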