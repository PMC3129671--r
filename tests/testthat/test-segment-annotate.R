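test_that("HPS is the product of per-locus homozygosity frequencies", {
  expect_equal(hps(c(0.5, 0.5)), 0.25)
  expect_equal(hps(c(0.3, 1, 1, 1)), 0.3)  # fixed loci do not penalise
  expect_error(hps(c(0.5, NA)), "missing Freq_HOM")
  # log-space computation matches the direct product
  withr::local_seed(4)
  for (i in 1:50) {
    fh <- runif(sample(5:200, 1), 0.2, 1)
    expect_equal(hps(fh), prod(fh), tolerance = 1e-12)
  }
  # the 0.01 filter boundary around 0.8^k
  expect_gt(hps(rep(0.8, 20)), 0.01)
  expect_lt(hps(rep(0.8, 21)), 0.01)
})

test_that("MISL is the min over samples of per-sample maximum lengths", {
  segs <- tibble::tibble(
    sample_id = c("a", "a", "b"), chromosome = "1",
    length_bp = c(300000, 120000, 200000)
  )
  m <- compute_misl(segs)
  expect_equal(m$misl_chr$misl_bp, 200000)
  expect_equal(m$misl_gw, 200000)
  # random fixture vs brute-force two-level min/max, plus subsets
  withr::local_seed(9)
  rs <- tibble::tibble(
    sample_id = sample(paste0("s", 1:5), 200, replace = TRUE),
    chromosome = sample(c("1", "2", "3"), 200, replace = TRUE),
    length_bp = rexp(200, 1e-5)
  )
  m2 <- compute_misl(rs, subsets = list(auto = c("1", "2")))
  for (chr in c("1", "2", "3")) {
    per_sample <- vapply(paste0("s", 1:5), function(s) {
      v <- rs$length_bp[rs$sample_id == s & rs$chromosome == chr]
      if (length(v)) max(v) else NA_real_
    }, numeric(1))
    expect_equal(m2$misl_chr$misl_bp[m2$misl_chr$chromosome == chr],
                 min(per_sample, na.rm = TRUE))
  }
  expect_equal(m2$misl_gw, min(m2$misl_chr$misl_bp))
  expect_equal(unname(m2$misl_subset["auto"]),
               min(m2$misl_chr$misl_bp[m2$misl_chr$chromosome %in% c("1", "2")]))
})

test_that("MAD score standardises length against the local distribution", {
  # hand computation: m = 105, raw MAD = 5, c*d = 7.413
  block <- matrix(c(100, 100, 110, 120), ncol = 1)
  expect_equal(mad_score(400, block), (400 - 105) / (1.4826 * 5))
  # centring: length at the median scores 0
  expect_equal(mad_score(105, block), 0)
  # duplicate columns collapse to one representative
  expect_equal(mad_score(400, cbind(block, block, block)),
               mad_score(400, block))
  # zero spread: +Inf above the median, 0 otherwise
  tied <- matrix(rep(100, 4), ncol = 1)
  expect_equal(mad_score(400, tied), Inf)
  expect_equal(mad_score(50, tied), 0)
  # all-zero vectors are skipped
  expect_true(is.na(mad_score(400, matrix(0, 4, 1))))
  # uniform population: every segment scores 0
  expect_equal(mad_score(200, matrix(200, 10, 3)), 0)
})

test_that("founder haplotype frequency counts near-matching panel rows", {
  withr::local_seed(15)
  n_loci <- 300
  base <- rbinom(n_loci, 1, 0.5)
  hap <- matrix(rbinom(120 * n_loci, 1, 0.5), nrow = 120)
  hap[1:30, ] <- rep(base, each = 30)  # 30 exact copies
  panel <- phased_panel(hap, sample_id = paste0("s", rep(1:60, each = 2)),
                        population = rep("p", 120))
  calls <- ifelse(base == 1, 2L, 0L)
  expect_equal(founder_hap_freq(calls, panel, seq_len(n_loci)), 0.25)
  # tolerance is max(0.01 * L, 1): L = 300 allows 3 mismatches
  hap2 <- hap
  hap2[31, ] <- base; hap2[31, 1:3] <- 1 - base[1:3]  # 3 mismatches: in
  hap2[32, ] <- base; hap2[32, 1:4] <- 1 - base[1:4]  # 4 mismatches: out
  panel2 <- phased_panel(hap2, panel$sample_id, panel$population)
  expect_equal(founder_hap_freq(calls, panel2, seq_len(n_loci)), 31 / 120)
  # L = 50: tolerance max(0.5, 1) = 1 mismatch
  short <- seq_len(50)
  hap3 <- matrix(1 - base[short], nrow = 4, ncol = 50, byrow = TRUE)
  hap3[1, ] <- base[short]
  hap3[2, ] <- base[short]; hap3[2, 1] <- 1 - base[1]   # 1 mismatch: in
  hap3[3, ] <- base[short]; hap3[3, 1:2] <- 1 - base[1:2]  # 2: out
  panel3 <- phased_panel(hap3, paste0("s", rep(1:2, each = 2)), rep("p", 4))
  expect_equal(founder_hap_freq(calls[short], panel3, short), 2 / 4)
  # excluding the carrier sample removes its two haplotypes
  expect_equal(founder_hap_freq(calls[short], panel3, short,
                                exclude_sample = "s1"), 0)
  # monomorphic matching panel -> frequency 1
  mono <- phased_panel(matrix(rep(base, 6), nrow = 6, byrow = TRUE),
                       paste0("s", rep(1:3, each = 2)), rep("p", 6))
  expect_equal(founder_hap_freq(calls, mono, seq_len(n_loci)), 1)
})

test_that("mappable length subtracts gaps larger than 500 kb", {
  expect_equal(mappable_length(c(1, 1000001)), 0)
  expect_equal(mappable_length(seq(1, 999001, by = 1000)), 999000)
  withr::local_seed(3)
  gaps <- sample(c(1000, 2000, 7e5, 1e6), 50, replace = TRUE,
                 prob = c(.6, .3, .05, .05))
  pos <- cumsum(c(1, gaps))
  expect_equal(mappable_length(pos),
               max(pos) - min(pos) - sum(gaps[gaps > 5e5]))
  expect_error(mappable_length(100), "at least 2")
})

test_that("coverage curves cumulate interpolated lengths per individual", {
  gm <- make_gm(matrix(0L, 2, 10), positions = seq(1L, 999001L, length.out = 10))
  segs <- tibble::tibble(
    sample_id = c("s1", "s2"), population = "p", chromosome = "1",
    length_bp = c(199800, 599400), snp_count = c(10L, 10L),
    masked_cnv = FALSE
  )
  cc <- coverage_curves(segs, gm, cutoffs = c(0, 1e5, 2e5, 1e6))
  # s1 contributes 0.2, s2 contributes 0.6 of the 999 kb mappable length
  expect_equal(cc$median_proportion, c(0, 0, 0.1, 0.4))
  # brute-force oracle on a random fixture
  withr::local_seed(12)
  gm2 <- make_gm(matrix(0L, 3, 11), positions = seq(1L, 2000001L, length.out = 11))
  rs <- tibble::tibble(
    sample_id = sample(paste0("s", 1:3), 30, replace = TRUE),
    population = "p", chromosome = "1",
    length_bp = round(runif(30, 1e4, 9e5)), snp_count = 5L,
    masked_cnv = FALSE
  )
  cuts <- seq(0, 1e6, by = 5e4)
  got <- coverage_curves(rs, gm2, cutoffs = cuts)
  want <- vapply(cuts, function(ct) {
    median(vapply(paste0("s", 1:3), function(s) {
      v <- rs$length_bp[rs$sample_id == s]
      sum(v[v <= ct]) / 2000000
    }, numeric(1)))
  }, numeric(1))
  expect_equal(got$median_proportion, want)
})

test_that("interval intersection matches the quadratic oracle", {
  a <- tibble::tibble(chromosome = "1", start_bp = 100L, end_bp = 200L)
  b <- tibble::tibble(chromosome = "1", start_bp = 150L, end_bp = 300L)
  expect_equal(intersect_segments(a, b)$n_hits, 1L)
  expect_equal(intersect_segments(b, a)$n_hits, 1L)
  far <- tibble::tibble(chromosome = "1", start_bp = 900L, end_bp = 950L)
  expect_equal(intersect_segments(a, far)$n_hits, 0L)
  withr::local_seed(2)
  mk <- function(n) {
    s <- sample.int(1e6, n)
    tibble::tibble(chromosome = sample(c("1", "2"), n, replace = TRUE),
                   start_bp = s, end_bp = s + sample.int(5e4, n))
  }
  A <- mk(300); B <- mk(300)
  got <- intersect_segments(A, B)
  for (i in seq_len(nrow(A))) {
    hits <- which(B$chromosome == A$chromosome[i] &
                    B$start_bp <= A$end_bp[i] & B$end_bp >= A$start_bp[i])
    expect_equal(sort(got$hits[[i]]), hits)
  }
})

test_that("annotate_segments flags the HPS-passing analysis set", {
  sim <- fixture_sim()
  segs <- sim$segs
  in_set <- segs$hps_ex <= 0.01
  expect_true(any(in_set))
  expect_true(all(is.na(segs$mad_score[!in_set])))
  expect_true(all(!is.na(segs$mad_score[in_set])))
  expect_true(all(segs$hps_ex > 0 & segs$hps_ex <= 1))
  expect_true(all(segs$hps_in > 0 & segs$hps_in <= 1))
  expect_true(all(segs$founder_hap_freq[in_set] >= 0 &
                    segs$founder_hap_freq[in_set] <= 1))
})
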