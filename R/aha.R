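#' Two-sample Cramer-von Mises statistic on segment lengths
#'
#' The discrete minimum-distance statistic: both samples' right-continuous
#' ECDFs are evaluated at every unique value in the combined sample and
#' `omega2` is the sum of the squared differences.  The statistic is
#' symmetric, depends only on ranks, and is 0 iff the ECDFs coincide at
#' the combined support.
#'
#' @param values_a,values_b Numeric vectors (non-empty after removing
#'   `NA`).
#' @return `omega2 >= 0`.
#' @export
cvm_omega2 <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) == 0 || length(values_b) == 0) {
    abort("both samples must be non-empty")
  }
  x <- sort(unique(c(values_a, values_b)))
  fa <- ecdf(values_a)(x)
  fb <- ecdf(values_b)(x)
  sum((fa - fb)^2)
}

#' Permutation test for the two-sample Cramer-von Mises statistic
#'
#' Values are pooled, group labels randomly rearranged (preserving group
#' sizes) `n_perm` times, and the achieved significance level computed as
#' the proportion of permuted statistics at least as large as the observed
#' one.  With `plus_one = TRUE` both numerator and denominator are
#' incremented, guaranteeing a strictly positive level.
#'
#' @param values_a,values_b Numeric vectors.
#' @param n_perm Number of permutations (at least 100).
#' @param seed Integer seed for reproducibility.
#' @param plus_one Use the (b + 1)/(B + 1) convention (default `FALSE`).
#' @return A one-row tibble: `omega2`, `asl`, `n_perm`, `seed`.
#' @export
cvm_permutation_test <- function(values_a, values_b, n_perm = 1000,
                                 seed = 1L, plus_one = FALSE) {
  stopifnot(n_perm >= 100)
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) == 0 || length(values_b) == 0) {
    abort("both samples must be non-empty")
  }
  obs <- cvm_omega2(values_a, values_b)
  perm <- cvm_perm_stats(values_a, values_b, n_perm, seed)
  n_ge <- sum(perm >= obs - 1e-12)
  asl <- if (plus_one) (n_ge + 1) / (n_perm + 1) else n_ge / n_perm
  tibble(omega2 = obs, asl = asl, n_perm = as.integer(n_perm),
         seed = as.integer(seed))
}

# Vector of n_perm permuted omega2 statistics.  The statistic reduces to
# sums over the pooled sorted order: with weights +1/nA for A labels and
# -1/nB for B labels, F_A - F_B at each support point is the running sum,
# and omega2 sums its square at the last index of each unique value.
cvm_perm_stats <- function(values_a, values_b, n_perm, seed) {
  na <- length(values_a); nb <- length(values_b)
  pool <- c(values_a, values_b)
  ord <- order(pool)
  sorted <- pool[ord]
  endpoint <- c(diff(sorted) > 0, TRUE)
  w_a <- 1 / na; w_b <- -1 / nb
  n <- na + nb
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  vapply(seq_len(n_perm), function(b) {
    lab_a <- logical(n)
    lab_a[sample.int(n, na)] <- TRUE
    w <- ifelse(lab_a, w_a, w_b)
    d <- cumsum(w)
    sum(d[endpoint]^2)
  }, numeric(1))
}

#' Per-locus Cramer-von Mises scan between two groups' ISLMs
#'
#' At each locus the two groups' intersecting-segment-length vectors
#' (masked cells dropped, zeros retained by default) are compared with
#' [cvm_omega2()]; loci whose statistic reaches `screen_threshold` are
#' additionally assessed with the permutation test.  Matrices must be
#' column-aligned on the same loci.
#'
#' @param islm_a,islm_b `hz_islm` objects for the two groups (e.g. two
#'   populations' rows of a shared matrix, or cases and controls).
#' @param n_perm Permutations per tested locus (0 disables testing).
#' @param seed Integer seed; each locus uses an offset of it.
#' @param screen_threshold Only loci with `omega2` at or above this value
#'   are permutation-tested (default 0: all loci when `n_perm > 0`).
#' @param drop_zeros Drop zero-length entries from both samples before
#'   comparison (default `FALSE`).
#' @return A tibble: `locus_id`, `position_bp`, `omega2`, `asl`
#'   (`NA` where not tested), `n_perm`.
#' @export
cvm_scan <- function(islm_a, islm_b, n_perm = 0, seed = 1L,
                     screen_threshold = 0, drop_zeros = FALSE) {
  if (!identical(islm_a$loci$id, islm_b$loci$id)) {
    abort("ISLMs are not aligned on the same loci")
  }
  n_loci <- ncol(islm_a$values)
  omega2 <- rep(NA_real_, n_loci)
  asl <- rep(NA_real_, n_loci)
  for (j in seq_len(n_loci)) {
    va <- islm_a$values[, j]; va <- va[!is.na(va)]
    vb <- islm_b$values[, j]; vb <- vb[!is.na(vb)]
    if (drop_zeros) { va <- va[va > 0]; vb <- vb[vb > 0] }
    if (length(va) == 0 || length(vb) == 0) next
    omega2[j] <- cvm_omega2(va, vb)
    if (n_perm > 0 && omega2[j] >= screen_threshold) {
      asl[j] <- cvm_permutation_test(va, vb, n_perm = n_perm,
                                     seed = seed + j)$asl
    }
  }
  tibble(
    locus_id = islm_a$loci$id,
    position_bp = islm_a$loci$position_bp,
    omega2 = omega2,
    asl = asl,
    n_perm = as.integer(n_perm)
  )
}
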