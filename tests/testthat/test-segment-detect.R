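test_that("gap threshold is the exponential of the log-gap upper whisker", {
  # equal gaps: zero spread, threshold equals the gap itself
  expect_equal(compute_gap_thresholds(seq(1, 101 * 1000, by = 1000)), 1000)
  # constructed hinges: log-gaps 6,7,8,9,10 -> hinges 7 and 9, whisker 12
  pos <- cumsum(c(1, exp(6:10)))
  expect_equal(compute_gap_thresholds(pos), exp(9 + 1.5 * 2))
  # random gaps: agree with an independent fivenum-from-sorted computation
  withr::local_seed(5)
  gaps <- exp(rnorm(200, 7, 1))
  lg <- sort(log(gaps))
  n <- length(lg)
  # boxplot hinges from the sorted values, written out from the definition
  h <- (floor((n + 3) / 2)) / 2
  q1 <- (lg[floor(h)] + lg[ceiling(h)]) / 2
  q3 <- (lg[n + 1 - floor(h)] + lg[n + 1 - ceiling(h)]) / 2
  expect_equal(compute_gap_thresholds(cumsum(c(1, gaps))),
               exp(q3 + 1.5 * (q3 - q1)))
  expect_error(compute_gap_thresholds(c(1, 2)), "at least 3")
})

test_that("run detection splits at heterozygotes and spans missing calls", {
  r <- detect_runs(c(0L, 0L, 2L, 1L, 0L, 0L))
  expect_equal(r$start_idx, c(1L, 5L))
  expect_equal(r$end_idx, c(3L, 6L))
  r2 <- detect_runs(c(0L, 3L, 0L))
  expect_equal(nrow(r2), 1L)
  expect_equal(c(r2$start_idx, r2$end_idx, r2$nocall_count), c(1L, 3L, 1L))
  expect_equal(nrow(detect_runs(rep(1L, 10))), 0L)
  # runs are trimmed to their outermost homozygous calls
  r3 <- detect_runs(c(3L, 0L, 0L, 3L))
  expect_equal(c(r3$start_idx, r3$end_idx), c(2L, 3L))
})

test_that("het absorption follows the 1% proportion rule exactly", {
  seg_spans <- function(calls, params = het_only_params()) {
    s <- detect_segments(make_gm1(calls), params)
    cbind(s$start_idx, s$end_idx)
  }
  # 300 + 1 het + 300: 1/601 = 0.17% -> merged
  calls_ok <- c(rep(0L, 300), 1L, rep(2L, 300))
  expect_equal(seg_spans(calls_ok), cbind(1L, 601L))
  # 40 + 1 het + 40: 1/81 = 1.23% -> not merged
  calls_no <- c(rep(0L, 40), 1L, rep(2L, 40))
  expect_equal(seg_spans(calls_no), cbind(c(1L, 42L), c(40L, 81L)))
  # zero hets: identity
  expect_equal(seg_spans(rep(0L, 50)), cbind(1L, 50L))
})

test_that("scan-ahead halts at a 3% window but proceeds at 1%", {
  params <- detection_params(
    gap_width_join_thresholds = permissive_gap_thresholds(),
    gap_width_scan_thresholds = permissive_gap_thresholds(),
    max_het_proportion = 0.01, scan_ahead_het_threshold = 0.02
  )
  # 1000 homs then sustained heterozygosity of one het per 26 SNPs: the
  # trailing 100-SNP window reaches 3 hets (3%) and halts the scan, even
  # though absorbing everything would keep global het at 4/1104 = 0.36%
  calls_stop <- c(rep(0L, 1000), 1L, rep(0L, 25), 1L, rep(0L, 25), 1L,
                  rep(0L, 25), 1L, rep(0L, 25))
  segs <- detect_segments(make_gm1(calls_stop), params)
  expect_equal(segs$end_idx[1], 1052L)
  expect_equal(nrow(segs), 3L)
  # 1000 homs then 1 het in the next 100 (1% local, global 1/1100): merged
  calls_go <- c(rep(0L, 1000), 1L, rep(0L, 99))
  segs_go <- detect_segments(make_gm1(calls_go), params)
  expect_equal(nrow(segs_go), 1L)
  expect_equal(c(segs_go$start_idx, segs_go$end_idx), c(1L, 1100L))
})

test_that("gap joining honours flank-proportion rules per gap range", {
  tb <- tibble::tibble(
    gap_min_bp = c(1e4, 5e5),
    gap_max_bp = c(5e5, Inf),
    min_density_snp_per_kb = c(0, 0),
    min_flank_proportion = c(0.1, 0.5)
  )
  params <- detection_params(
    gap_width_join_thresholds = tb, gap_width_scan_thresholds = tb,
    max_het_proportion = 0.01, scan_ahead_het_threshold = 0.02
  )
  # two 500 kb runs flanking a 100 kb gap; rule needs flanks >= 10 kb: joined
  pos_join <- c(seq(1, 5e5, by = 1000), seq(6e5, 11e5, by = 1000))
  segs <- detect_segments(make_gm1(rep(0L, length(pos_join)), pos_join), params)
  expect_equal(nrow(segs), 1L)
  # 10 kb run at the edge of a 3 Mb gap; needs flank >= 1.5 Mb: truncated
  pos_trunc <- c(seq(1, 1e4, by = 1000), seq(3e6, 3.5e6, by = 1000))
  segs_t <- detect_segments(make_gm1(rep(0L, length(pos_trunc)), pos_trunc),
                            params)
  expect_equal(nrow(segs_t), 2L)
  expect_equal(segs_t$end_bp[1], 9001)
  # gap below the lowest range boundary: ordinary spacing, always joined
  pos_small <- c(seq(1, 1e5, by = 1000), seq(1.05e5, 2e5, by = 1000))
  expect_equal(nrow(detect_segments(make_gm1(rep(0L, length(pos_small)),
                                             pos_small), params)), 1L)
})

test_that("detection equals the exhaustive enumerator on random fixtures", {
  withr::local_seed(71)
  params <- het_only_params()
  for (rep in 1:60) {
    calls <- random_calls(200)
    pos <- cumsum(sample(c(500:1500, 5e4), 200, replace = TRUE,
                         prob = c(rep(1, 1001), 20)))
    segs <- detect_segments(make_gm1(calls, pos), params)
    expect_equal(unname(cbind(segs$start_idx, segs$end_idx)),
                 unname(oracle_segments(calls)))
  }
})

test_that("detection is deterministic and segments never overlap", {
  withr::local_seed(8)
  calls <- matrix(random_calls(400 * 6, p_het = 0.05), nrow = 6)
  gm <- make_gm(calls)
  s1 <- detect_segments(gm)
  s2 <- detect_segments(gm)
  expect_identical(s1, s2)
  for (sid in unique(s1$sample_id)) {
    sub <- s1[s1$sample_id == sid, ]
    if (nrow(sub) > 1) {
      expect_true(all(diff(sub$start_idx) > 0))
      expect_true(all(sub$start_idx[-1] > sub$end_idx[-nrow(sub)]))
    }
  }
  expect_true(all(s1$het_count / s1$snp_count <= 0.01 + 1e-12))
  expect_true(all(s1$snp_count >= 2))
})

test_that("raising the het tolerance only extends or merges segments", {
  withr::local_seed(31)
  for (rep in 1:20) {
    calls <- random_calls(500, p_het = 0.01, p_mis = 0.02)
    lo <- detect_segments(make_gm1(calls), het_only_params(0.005))
    hi <- detect_segments(make_gm1(calls), het_only_params(0.02))
    # every low-threshold segment lies inside one high-threshold segment
    for (i in seq_len(nrow(lo))) {
      expect_true(any(hi$start_idx <= lo$start_idx[i] &
                        hi$end_idx >= lo$end_idx[i]))
    }
  }
})

test_that("segment flags mark missingness, density and CNV intersection", {
  # 10% no-calls -> high_missing
  calls <- rep(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 3L), 10)
  segs <- detect_segments(make_gm1(calls), het_only_params())
  expect_true(all(segs$high_missing))
  # 1 SNP per 10 kb <= 0.2/kb -> low_density
  segs_ld <- detect_segments(make_gm1(rep(0L, 50), seq_len(50) * 10000),
                             het_only_params())
  expect_true(all(segs_ld$low_density))
  segs_hd <- detect_segments(make_gm1(rep(0L, 50), seq_len(50) * 1000),
                             het_only_params())
  expect_false(any(segs_hd$low_density))
  # CNV covering > 50% of loci -> masked_cnv
  mask <- region_mask("1", 1L, 30000L, "cnv", 0.5)
  segs_cnv <- detect_segments(make_gm1(rep(0L, 50)), het_only_params(),
                              mask = mask)
  expect_true(all(segs_cnv$masked_cnv))
  mask_small <- region_mask("1", 1L, 10000L, "cnv", 0.5)
  segs_small <- detect_segments(make_gm1(rep(0L, 50)), het_only_params(),
                                mask = mask_small)
  expect_false(any(segs_small$masked_cnv))
})
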