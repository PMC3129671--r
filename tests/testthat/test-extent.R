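test_that("ISLM cells hold the covering segment's length", {
  gm <- make_gm(matrix(0L, 2, 5))
  segs <- tibble::tibble(
    sample_id = "s1", population = "p", chromosome = "1",
    start_bp = 1000L, end_bp = 10999L, start_idx = 1L, end_idx = 3L,
    length_bp = 10000L, masked_cnv = FALSE
  )
  islm <- build_islm(segs, gm, units = "bp", filter_hps = Inf)
  expect_equal(unname(islm$values["s1", ]), c(10000, 10000, 10000, 0, 0))
  expect_equal(unname(islm$values["s2", ]), rep(0, 5))
  # masked segments become NA, not 0
  segs$masked_cnv <- TRUE
  islm_m <- build_islm(segs, gm, units = "bp", filter_hps = Inf)
  expect_equal(unname(islm_m$values["s1", 1:3]), rep(NA_real_, 3))
  # random fixture: per-locus scan oracle
  withr::local_seed(23)
  sim <- fixture_sim()
  islm_r <- build_islm(sim$segs, sim$sim$gm, units = "bp")
  segs_f <- sim$segs[sim$segs$hps_ex <= 0.01, ]
  for (j in sample(ncol(islm_r$values), 40)) {
    for (s in sample(rownames(islm_r$values), 4)) {
      hit <- segs_f[segs_f$sample_id == s & segs_f$start_idx <= j &
                      segs_f$end_idx >= j, ]
      want <- if (nrow(hit) == 0) 0 else
        if (isTRUE(hit$masked_cnv[1])) NA_real_ else hit$length_bp[1]
      expect_equal(islm_r$values[s, j], want)
    }
  }
})

test_that("centimorgan conversion uses arm rates with proportional splits", {
  expect_equal(bp_to_cm(1e6, 1.3), 1.3)
  expect_equal(bp_to_cm(0, 2), 0)
  arms <- tibble::tibble(
    chromosome = "1", arm = c("p", "q"),
    start_bp = c(1L, 1000001L), end_bp = c(1000000L, 3000000L),
    cm_per_mb = c(1, 2)
  )
  # 2 Mb spanning the boundary 50/50: 1 cM + 2 cM
  expect_equal(interval_cm("1", 1, 2000000, arms), 1 * 1 + 1 * 2)
  expect_error(interval_cm("2", 1, 10, arms), "no arm rates")
  expect_error(interval_cm("1", 2999999, 3000002, arms), "not fully covered")
})

test_that("autozygous capping replaces extreme cells with the column max", {
  gm <- make_gm(matrix(0L, 3, 3))
  segs <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"), population = "p", chromosome = "1",
    start_bp = 1000L, end_bp = 3000L, start_idx = 1L,
    end_idx = c(3L, 3L, 2L),
    length_bp = c(5e6L, 2e5L, 15e4L), masked_cnv = FALSE,
    mad_score = c(30, 2, 1)
  )
  islm <- build_islm(segs, gm, units = "bp", filter_hps = Inf)
  capped <- mask_islm_autozygous(islm)
  expect_equal(unname(capped$values[, 1]), c(2e5, 2e5, 15e4))
  expect_equal(unname(capped$values[, 3]), c(2e5, 2e5, 0))
  expect_true(all(capped$capped[1, 1:3]))
  # no autozygous segments: identity
  segs2 <- segs; segs2$mad_score <- c(1, 2, 1)
  islm2 <- build_islm(segs2, gm, units = "bp", filter_hps = Inf)
  expect_equal(mask_islm_autozygous(islm2)$values, islm2$values)
  # column with only autozygous coverage drops to 0
  segs3 <- segs[1, ]
  islm3 <- build_islm(segs3, gm, units = "bp", filter_hps = Inf)
  capped3 <- suppressMessages(mask_islm_autozygous(islm3))
  expect_equal(unname(capped3$values[1, ]), c(0, 0, 0))
})

test_that("PE_mat rows are type-7 quantiles, non-decreasing across levels", {
  sim <- fixture_sim()
  pm <- pe_mat(sim$islm, "popA")
  expect_equal(dim(pm$values), c(ncol(sim$islm$values), 101L))
  mono <- apply(pm$values, 1, function(r) all(diff(r) >= -1e-12, na.rm = TRUE))
  expect_true(all(mono))
  # sort-based oracle at all 101 levels for a sample of loci
  rows <- sim$islm$samples$population == "popA"
  withr::local_seed(6)
  for (j in sample(ncol(sim$islm$values), 25)) {
    v <- sim$islm$values[rows, j]
    v <- v[!is.na(v)]
    want <- vapply(0:100 / 100, function(p) oracle_quantile7(v, p), numeric(1))
    expect_equal(unname(pm$values[j, ]), want)
  }
  # boundary examples
  gm <- make_gm(matrix(0L, 4, 1))
  segs <- tibble::tibble(sample_id = "s4", population = "p", chromosome = "1",
                         start_bp = 1000L, end_bp = 1000L, start_idx = 1L,
                         end_idx = 1L, length_bp = 100000L, masked_cnv = FALSE)
  m <- build_islm(segs, gm, units = "bp", filter_hps = Inf)
  pm2 <- pe_mat(m, "p")
  expect_equal(pm2$values[1, 1], 0)
  expect_equal(pm2$values[1, 101], 100000)
})

test_that("ext_AUC integrates the reversed-length ECDF over the shared bounds", {
  # hand-worked example: {0.1, 0.1, 0.2, 0.4} cM -> 0.10
  gm <- make_gm(matrix(0L, 4, 1))
  mk_islm <- function(lengths) {
    structure(list(
      values = matrix(lengths, ncol = 1),
      capped = matrix(FALSE, length(lengths), 1),
      units = "cm", chromosome = "1",
      loci = gm$loci,
      samples = tibble::tibble(id = paste0("s", seq_along(lengths)),
                               population = "p")
    ), class = "hz_islm")
  }
  expect_equal(ext_auc(mk_islm(c(0.1, 0.1, 0.2, 0.4)), "p")$ext_auc, 0.10)
  # no intersecting segments anywhere -> 0
  expect_equal(ext_auc(mk_islm(c(0, 0, 0)), "p")$ext_auc, 0)
  # a single distinct positive value -> bounds collapse -> 0
  expect_equal(ext_auc(mk_islm(c(0.5, 0.5, 0)), "p")$ext_auc, 0)
  # linear scaling: lengths x k -> ext_AUC x k
  withr::local_seed(18)
  for (i in 1:20) {
    v <- round(c(rexp(12, 2), rep(0, 3)), 3)
    k <- runif(1, 0.5, 5)
    a1 <- ext_auc(mk_islm(v), "p")$ext_auc
    ak <- ext_auc(mk_islm(v * k), "p")$ext_auc
    expect_equal(ak, k * a1, tolerance = 1e-10)
  }
  # duplication of the whole population leaves the ECDF unchanged
  v <- c(0.3, 0.8, 0, 1.4)
  expect_equal(ext_auc(mk_islm(c(v, v)), "p")$ext_auc,
               ext_auc(mk_islm(v), "p")$ext_auc)
  # exact step integration equals adaptive quadrature of the ECDF
  for (i in 1:40) {
    v <- c(rexp(15, 1), rep(0, sample(0:5, 1)))
    rev_v <- -v[v > 0]
    lower <- min(rev_v); upper <- max(rev_v)
    if (upper <= lower) next
    F <- ecdf(-v)
    # adaptive quadrature piecewise between the jump points, so the
    # integrator only ever sees a smooth (constant) integrand
    kn <- sort(unique(c(lower, upper, knots(F)[knots(F) > lower &
                                                 knots(F) < upper])))
    quad <- sum(vapply(seq_len(length(kn) - 1), function(k) {
      integrate(function(x) F(x), kn[k], kn[k + 1], rel.tol = 1e-10,
                stop.on.error = FALSE)$value
    }, numeric(1)))
    expect_equal(ext_auc(mk_islm(v), "p")$ext_auc, quad, tolerance = 1e-6)
  }
})

test_that("ext_AUC ranks are empirical cumulative probabilities", {
  tr <- tibble::tibble(
    locus_id = paste0("L", 1:6), chromosome = "1", position_bp = 1:6,
    population = "p", ext_auc = c(0.2, 0.5, 0.5, 0.1, 0.9, 0.3)
  )
  r <- ext_auc_rank(tr)
  expect_equal(r$rank[5], 1)
  expect_equal(r$rank, vapply(tr$ext_auc,
                              function(x) mean(tr$ext_auc <= x), numeric(1)))
  # all equal -> all ranks 1
  tr2 <- tr; tr2$ext_auc <- rep(0.4, 6)
  expect_equal(ext_auc_rank(tr2)$rank, rep(1, 6))
})
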