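# Build a peak tibble by hand with consistent valley indices, so merge and
# region rules can be exercised in isolation.
mk_peaks <- function(heights, valleys) {
  stopifnot(length(valleys) == length(heights) - 1)
  n <- length(heights)
  v_all <- c(0, valleys, 0)
  tibble::tibble(
    apex_bp = seq_len(n) * 1000L,
    low_valley_bp = seq_len(n) * 1000L - 500L,
    high_valley_bp = seq_len(n) * 1000L + 500L,
    height = heights,
    low_valley_value = v_all[seq_len(n)],
    high_valley_value = v_all[seq_len(n) + 1L],
    apex_idx = seq_len(n) * 10L,
    low_valley_idx = seq_len(n) * 10L - 5L,
    high_valley_idx = seq_len(n) * 10L + 5L
  ) |>
    dplyr::mutate(low_valley_idx = c(1L, high_valley_idx[-n]))
}

test_that("spline smoothing preserves shape and locates extrema", {
  # constant input: flat fit with near-zero derivative
  n <- 100
  sm <- smooth_track(rep(2, n), seq_len(n) * 1000)
  expect_equal(sm$smooth, rep(2, n), tolerance = 1e-6)
  expect_true(all(abs(sm$deriv) < 1e-6))
  # single broad bump: exactly one apex near the true maximum
  x <- seq_len(200) * 1000
  bump <- exp(-((x - 1e5) / 6e4)^2)
  pk <- detect_peaks(smooth_track(bump, x))
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$apex_bp[1] - 1e5), 3000)
  # sine over several periods (well inside the knot budget): apexes within
  # one locus of the analytic ones
  xs <- seq_len(600) * 1000
  ys <- sin(2 * pi * xs / 2e5)
  pks <- detect_peaks(smooth_track(ys, xs))
  true_apex <- seq(5e4, max(xs), by = 2e5)
  interior <- pks$apex_bp > min(xs) + 1e5 & pks$apex_bp < max(xs) - 1e5
  for (a in pks$apex_bp[interior]) {
    expect_lte(min(abs(true_apex - a)), 1000 + 1e-9)  # within one locus
  }
  expect_error(smooth_track(rep(1, 10), 1:10), "too few")
})

test_that("peak detection finds apexes and flanking valleys", {
  # monotone track: no peaks
  xs <- seq_len(100) * 1000
  expect_equal(nrow(detect_peaks(smooth_track(xs / 1e5, xs))), 0L)
  # two bumps share the intervening valley
  ys <- exp(-((xs - 2.5e4) / 8e3)^2) + 0.8 * exp(-((xs - 7.5e4) / 8e3)^2)
  pk <- detect_peaks(smooth_track(ys, xs))
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$high_valley_bp[1], pk$low_valley_bp[2])
  expect_true(all(pk$low_valley_bp <= pk$apex_bp &
                    pk$apex_bp <= pk$high_valley_bp))
})

test_that("similar adjacent peaks merge under the 10% rule", {
  # heights 1.00 and 0.95 with valley 0.93: 5% and 7% -> merge
  m <- merge_peaks(mk_peaks(c(1.00, 0.95), 0.93))
  expect_equal(nrow(m), 1L)
  expect_equal(m$height, 1.00)
  expect_equal(m$low_valley_idx, 1L)
  expect_equal(m$high_valley_idx, 25L)
  # valley 0.80: 20% drop -> no merge
  expect_equal(nrow(merge_peaks(mk_peaks(c(1.00, 0.95), 0.80))), 2L)
  # heights 1.00 and 0.85: 15% height difference -> no merge
  expect_equal(nrow(merge_peaks(mk_peaks(c(1.00, 0.85), 0.99))), 2L)
  # single peak: identity
  expect_equal(nrow(merge_peaks(mk_peaks(1.0, numeric(0)))), 1L)
  # chains reach a fixpoint bounded by the initial count
  chain <- mk_peaks(c(1, 0.99, 0.98, 0.97), c(0.97, 0.965, 0.955))
  expect_equal(nrow(merge_peaks(chain)), 1L)
})

test_that("outlier peaks exceed the boxplot upper whisker", {
  pk <- mk_peaks(c(1, 1, 1, 1, 10), rep(0.2, 4))
  fl <- flag_outlier_peaks(pk)
  expect_equal(fl$outlier, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # all equal: whisker equals the value, nothing flagged
  expect_false(any(flag_outlier_peaks(mk_peaks(rep(2, 6), rep(0.2, 5)))$outlier))
  # fewer than 4 peaks: warning, none flagged
  expect_warning(fl3 <- flag_outlier_peaks(mk_peaks(c(1, 9), 0.5)), "fewer")
  expect_false(any(fl3$outlier))
  # random heights: agree with an independent fivenum computation
  withr::local_seed(10)
  h <- rexp(40)
  flr <- flag_outlier_peaks(mk_peaks(h, rep(0, 39)))
  fn <- fivenum(h)
  expect_equal(flr$outlier, h > fn[4] + 1.5 * (fn[4] - fn[2]))
})

test_that("adjoining outlier peaks merge into regions unless separated", {
  base <- mk_peaks(c(1.0, 0.9), 0.6)
  base$outlier <- TRUE
  r <- merge_outlier_regions(base)  # valley 0.6 > 0.45: not separated
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_peaks, 1L + 1L)
  expect_equal(r$start_bp, base$low_valley_bp[1])
  expect_equal(r$end_bp, base$high_valley_bp[2])
  sep <- mk_peaks(c(1.0, 0.9), 0.3)
  sep$outlier <- TRUE
  expect_equal(nrow(merge_outlier_regions(sep)), 2L)  # 0.3 < 0.45
  lone <- mk_peaks(1.0, numeric(0))
  lone$outlier <- TRUE
  expect_equal(nrow(merge_outlier_regions(lone)), 1L)
})

test_that("peak haplotype parameters maximise extent times probability", {
  # three-level grid: products {0.09, 0.25, 0.20} -> (0.5, 0.5)
  loci <- tibble::tibble(id = "L1", chromosome = "1", position_bp = 1000L,
                         allele_a = "A", allele_b = "B", arm = "p")
  pm <- structure(list(
    values = matrix(NA_real_, 1, 101), percentiles = 0:100,
    population = "p", units = "cm", chromosome = "1", loci = loci
  ), class = "hz_pemat")
  pm$values[1, ] <- 0
  pm$values[1, c(11, 51, 81)] <- c(0.1, 0.5, 1.0)  # percentiles 10, 50, 80
  peak <- tibble::tibble(low_valley_bp = 500, high_valley_bp = 1500,
                         chromosome = "1")
  got <- peak_haplotype_params(peak, pm)
  expect_equal(got$extent_min, 0.5)
  expect_equal(got$p_max, 0.5)
  expect_equal(got$freq_hap_exp, sqrt(0.5))
  expect_equal(got$freq_hap_max, 0)
  # p_max = 1 (fixed region) gives expected frequency 1
  pm$values[1, ] <- 1
  got1 <- peak_haplotype_params(peak, pm)
  expect_equal(got1$p_max, 1)
  expect_equal(got1$freq_hap_exp, 1)
  # maximality: no grid pair beats the chosen one (random fixture)
  sim <- fixture_sim()
  pmr <- pe_mat(sim$islm, "popA")
  peak_r <- tibble::tibble(
    low_valley_bp = quantile(pmr$loci$position_bp, 0.4),
    high_valley_bp = quantile(pmr$loci$position_bp, 0.6),
    chromosome = "1"
  )
  gr <- peak_haplotype_params(peak_r, pmr)
  sel <- pmr$loci$position_bp >= peak_r$low_valley_bp &
    pmr$loci$position_bp <= peak_r$high_valley_bp
  block <- pmr$values[sel, , drop = FALSE]
  prods <- sweep(block, 2, 1 - 0:100 / 100, `*`)
  expect_gte(gr$extent_min * gr$p_max + 1e-12, max(prods, na.rm = TRUE))
})

test_that("cross-population rank takes the windowed maximum", {
  tr <- tidyr::crossing(population = c("a", "b"),
                        position_bp = seq(1000, 10000, by = 1000))
  withr::local_seed(14)
  tr$rank <- runif(nrow(tr))
  peak <- tibble::tibble(low_valley_bp = 3000, high_valley_bp = 7000)
  got <- cross_population_rank(peak, tr)
  for (p in c("a", "b")) {
    sub <- tr[tr$population == p & tr$position_bp >= 3000 &
                tr$position_bp <= 7000, ]
    expect_equal(unname(got[p]), max(sub$rank))
  }
  # identical tracks give identical rank maps
  tr2 <- tr; tr2$rank <- rep(tr$rank[tr$population == "a"], 2)
  got2 <- cross_population_rank(peak, tr2)
  expect_equal(unname(got2["a"]), unname(got2["b"]))
})

test_that("fixed areas are maximal runs of positive 0th-percentile extent", {
  loci <- tibble::tibble(id = paste0("L", 1:5), chromosome = "1",
                         position_bp = c(1, 2, 3, 4, 5) * 1000L,
                         allele_a = "A", allele_b = "B", arm = "p")
  mk_pm <- function(v0) {
    vals <- matrix(0, 5, 101)
    vals[, 1] <- v0
    vals[, 101] <- pmax(v0, 1)
    structure(list(values = vals, percentiles = 0:100, population = "p",
                   units = "cm", chromosome = "1", loci = loci),
              class = "hz_pemat")
  }
  runs <- detect_fixed_areas(mk_pm(c(0, 5, 5, 0, 7)))
  expect_equal(runs$start_idx, c(2L, 5L))
  expect_equal(runs$end_idx, c(3L, 5L))
  expect_equal(runs$snp_count, c(2L, 1L))
  expect_equal(runs$extent, c(5, 7))
  expect_equal(nrow(detect_fixed_areas(mk_pm(rep(0, 5)))), 0L)
  # candidate filter uses pooled first quartiles
  pm_a <- mk_pm(c(3, 3, 3, 0, 1)); pm_a$population <- "a"
  pm_b <- mk_pm(c(0, 9, 9, 9, 0)); pm_b$population <- "b"
  many <- detect_fixed_areas(list(pm_a, pm_b))
  q1s <- quantile(many$snp_count, 0.25, names = FALSE)
  q1e <- quantile(many$extent, 0.25, names = FALSE)
  expect_equal(many$candidate, many$snp_count > q1s & many$extent > q1e)
  # per-population quartiles judge each population against itself
  per <- detect_fixed_areas(list(pm_a, pm_b), quartile_scope = "per_population")
  for (p in c("a", "b")) {
    sub <- per[per$population == p, ]
    expect_equal(sub$candidate,
                 sub$snp_count > quantile(sub$snp_count, 0.25, names = FALSE) &
                   sub$extent > quantile(sub$extent, 0.25, names = FALSE))
  }
})

test_that("peak recombination rates come from the genetic map window", {
  # uniform 1 cM/Mb map: rate 1 everywhere
  map <- tibble::tibble(chromosome = "1",
                        position_bp = seq(1, 2e6, by = 1e4),
                        cm = (seq(1, 2e6, by = 1e4) - 1) / 1e6)
  track <- tibble::tibble(position_bp = seq(5e5, 15e5, by = 1e4),
                          ext_auc = dnorm(seq(5e5, 15e5, by = 1e4), 1e6, 1e5))
  peak <- tibble::tibble(chromosome = "1", low_valley_bp = 5e5,
                         high_valley_bp = 15e5)
  got <- peak_recombination(peak, track, map)
  expect_equal(got$recomb_rate, 1, tolerance = 1e-9)
  # hotspot spanning the window: rate equals hand-computed delta-cM ratio
  gmap <- simulate_genetic_map(seq(1, 2e6, by = 1e4), base_rate = 1,
                               hotspots = tibble::tibble(start_bp = 9e5,
                                                         end_bp = 11e5,
                                                         rate = 10))
  got_h <- peak_recombination(peak, track, gmap$map)
  cm_at <- function(p) approx(gmap$map$position_bp, gmap$map$cm, xout = p)$y
  want <- (cm_at(got_h$window_end_bp) - cm_at(got_h$window_start_bp)) /
    ((got_h$window_end_bp - got_h$window_start_bp) / 1e6)
  expect_equal(got_h$recomb_rate, want)
  expect_gt(got_h$recomb_rate, 1)
  expect_error(peak_recombination(peak, track,
                                  map[map$position_bp < 8e5, ]),
               "does not cover")
})
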