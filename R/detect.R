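#' Detection parameters for homozygous segment extraction
#'
#' The detector is controlled by two gap-range tables (one for the joining
#' stage, one for the scan-ahead stage) and two heterozygosity thresholds.
#' Each gap-range row is a record
#' `(gap_min_bp, gap_max_bp, min_density_snp_per_kb, min_flank_proportion)`:
#' a gap whose size falls in `(gap_min_bp, gap_max_bp]` may only be spanned
#' when each flanking run is at least `min_flank_proportion` times the gap
#' size and the combined span's SNP density meets the row's minimum.  The
#' lowest `gap_min_bp` is `NA` by default and is derived per chromosome from
#' the inter-SNP gap distribution by [compute_gap_thresholds()]; gaps below
#' it are ordinary spacing and never split a run.  This structure lets very
#' long (autozygous-scale) segments span large gaps such as centromeres
#' while short segments are truncated at gap edges.
#'
#' @param gap_width_join_thresholds,gap_width_scan_thresholds Data frames
#'   with columns `gap_min_bp`, `gap_max_bp`, `min_density_snp_per_kb`,
#'   `min_flank_proportion`, ascending in gap size.
#' @param max_het_proportion Maximum proportion of heterozygous calls among
#'   a segment's non-missing calls (default 0.01).
#' @param scan_ahead_het_threshold Local heterozygosity level at which the
#'   scan-ahead stage stops examining further extension (default 0.02).
#' @param min_scan_window Minimum number of called SNPs a scanned window
#'   must contain before the local-heterozygosity threshold is applied
#'   (default 100); below it a proportion threshold of a few percent is not
#'   meaningfully estimable.
#' @param dense_window,max_dense_het Hard local cap: an extension may never
#'   cross a stretch whose heterozygosity exceeds `max_dense_het` within a
#'   sliding window of `dense_window` called SNPs (defaults 25 and 0.20).
#'   Such bursts mark real heterozygous sequence; crossing one would spend
#'   the segment-wide error budget on it.  Set `max_dense_het = 1` to
#'   disable.
#' @param min_snp_density SNP/kb density below which emitted segments are
#'   flagged `low_density` (default 0.2, one SNP per 5 kb).
#' @param max_nocall_rate No-call rate above which emitted segments are
#'   flagged `high_missing` (default 0.05).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(gap_width_join_thresholds = default_gap_thresholds(),
                             gap_width_scan_thresholds = default_gap_thresholds(),
                             max_het_proportion = 0.01,
                             scan_ahead_het_threshold = 0.02,
                             min_scan_window = 100,
                             dense_window = 25,
                             max_dense_het = 0.20,
                             min_snp_density = 0.2,
                             max_nocall_rate = 0.05) {
  check_ranges <- function(tb) {
    tb <- as_tibble(tb)
    stopifnot(all(c("gap_min_bp", "gap_max_bp", "min_density_snp_per_kb",
                    "min_flank_proportion") %in% names(tb)))
    gmin <- tb$gap_min_bp
    if (nrow(tb) > 1 && any(diff(tb$gap_max_bp) <= 0)) {
      abort("gap threshold rows must ascend in gap size")
    }
    tb
  }
  if (!(max_het_proportion >= 0 && max_het_proportion <= scan_ahead_het_threshold &&
        scan_ahead_het_threshold <= 1)) {
    abort("need 0 <= max_het_proportion <= scan_ahead_het_threshold <= 1")
  }
  structure(list(
    gap_width_join_thresholds = check_ranges(gap_width_join_thresholds),
    gap_width_scan_thresholds = check_ranges(gap_width_scan_thresholds),
    max_het_proportion = max_het_proportion,
    scan_ahead_het_threshold = scan_ahead_het_threshold,
    min_scan_window = min_scan_window,
    dense_window = dense_window,
    max_dense_het = max_dense_het,
    min_snp_density = min_snp_density,
    max_nocall_rate = max_nocall_rate
  ), class = "detection_params")
}

#' Default gap-range table
#'
#' Three ranges: modest gaps up to 50 kb need flanks of at least 2% of the
#' gap, intermediate gaps up to 500 kb need 10%, and very large gaps
#' (centromere scale) need flanks at least half the gap size, so only
#' autozygous-scale segments span them.  The first `gap_min_bp` is derived
#' per chromosome at detection time.
#'
#' @return A tibble of gap-range records.
#' @export
default_gap_thresholds <- function() {
  tibble(
    gap_min_bp = c(NA_real_, 5e4, 5e5),
    gap_max_bp = c(5e4, 5e5, Inf),
    min_density_snp_per_kb = c(0.1, 0.05, 0.01),
    min_flank_proportion = c(0.02, 0.1, 0.5)
  )
}

#' Single-range gap table that never splits runs at gaps
#'
#' Convenience for analyses and tests where gap structure is irrelevant:
#' one range covering all gap sizes with no density or flank requirement.
#'
#' @return A tibble with one gap-range record.
#' @export
permissive_gap_thresholds <- function() {
  tibble(gap_min_bp = NA_real_, gap_max_bp = Inf,
         min_density_snp_per_kb = 0, min_flank_proportion = 0)
}

#' Derive the lowest gap-range boundary from the inter-SNP gap distribution
#'
#' Inter-SNP gaps are log-transformed, a standard boxplot summary computed,
#' and the boundary returned as `exp(upper whisker)` where the upper whisker
#' is the upper hinge plus 1.5 times the inter-hinge spread.
#'
#' @param positions Sorted base-pair positions of one chromosome's loci
#'   (at least 3).
#' @return The gap boundary in bp.
#' @export
compute_gap_thresholds <- function(positions) {
  if (length(positions) < 3) abort("need at least 3 loci to derive a gap threshold")
  gaps <- diff(sort(positions))
  lg <- log(gaps)
  fn <- fivenum(lg)
  q1 <- fn[2]; q3 <- fn[4]
  exp(q3 + 1.5 * (q3 - q1))
}

# Fill the derived lowest boundary into a gap table for one chromosome.
resolve_gap_table <- function(tb, g0) {
  if (is.na(tb$gap_min_bp[1])) tb$gap_min_bp[1] <- g0
  tb
}

# Look up the gap-range row for a gap size; NA row index if below the table.
gap_rule_row <- function(tb, gap) {
  if (gap <= tb$gap_min_bp[1]) return(NA_integer_)
  i <- which(gap > tb$gap_min_bp & gap <= tb$gap_max_bp)
  if (length(i) == 0) nrow(tb) else i[1]
}

#' Detect runs of consecutive homozygous calls in one sample
#'
#' Stage 1 of the detector: maximal runs of calls in {homRef, homAlt}.
#' Missing calls do not break a run (they are counted per run) but
#' heterozygous calls do.  Runs are trimmed so that they start and end on a
#' homozygous call.
#'
#' @param calls Integer call vector for one sample on one chromosome.
#' @param positions Base-pair positions aligned with `calls`.
#' @return A tibble of runs: `start_idx`, `end_idx` (1-based indices into
#'   `calls`), `hom_count`, `het_count` (always 0 at this stage),
#'   `nocall_count`.
#' @export
detect_runs <- function(calls, positions = seq_along(calls)) {
  stopifnot(length(calls) == length(positions))
  hom <- calls == CALL_HOMREF | calls == CALL_HOMALT
  het <- calls == CALL_HET
  n <- length(calls)
  if (n == 0 || !any(hom)) return(empty_runs())
  # pieces are the het-free intervals; trim each to its outermost hom calls
  grp <- cumsum(het) + 1L
  hom_idx <- which(hom)
  hom_grp <- grp[hom_idx]
  first <- !duplicated(hom_grp)
  last <- !duplicated(hom_grp, fromLast = TRUE)
  s <- hom_idx[first]
  e <- hom_idx[last]
  cs_hom <- cumsum(hom)
  cs_mis <- c(0L, cumsum(calls == CALL_MISSING))
  tibble(
    start_idx = as.integer(s), end_idx = as.integer(e),
    hom_count = as.integer(cs_hom[e] - cs_hom[s] + 1L),
    het_count = 0L,
    nocall_count = as.integer(cs_mis[e + 1L] - cs_mis[s])
  )
}

empty_runs <- function() {
  tibble(start_idx = integer(), end_idx = integer(), hom_count = integer(),
         het_count = integer(), nocall_count = integer())
}

run_stats <- function(runs, calls) {
  cs <- call_cumsums(calls)
  s <- runs$start_idx; e <- runs$end_idx
  runs$hom_count <- as.integer(cs$hom[e + 1L] - cs$hom[s])
  runs$het_count <- as.integer(cs$het[e + 1L] - cs$het[s])
  runs$nocall_count <- as.integer(cs$mis[e + 1L] - cs$mis[s])
  runs
}

# Leading-zero cumulative counts so that count over [a, b] is cs[b+1] - cs[a].
call_cumsums <- function(calls) {
  list(
    hom = c(0L, cumsum(calls == CALL_HOMREF | calls == CALL_HOMALT)),
    het = c(0L, cumsum(calls == CALL_HET)),
    mis = c(0L, cumsum(calls == CALL_MISSING)),
    called = c(0L, cumsum(calls != CALL_MISSING))
  )
}

# Does spanning `gap` (bp) with flanks of the given bp lengths satisfy the
# rule table?  Density is the combined span's SNP/kb.
gap_join_ok <- function(tb, gap, left_bp, right_bp, density_snp_per_kb) {
  row <- gap_rule_row(tb, gap)
  if (is.na(row)) return(TRUE)
  left_bp >= tb$min_flank_proportion[row] * gap &&
    right_bp >= tb$min_flank_proportion[row] * gap &&
    density_snp_per_kb >= tb$min_density_snp_per_kb[row]
}

#' Split or join runs across large inter-SNP gaps
#'
#' Stage 2: inside each homozygous run, gaps exceeding the lowest gap-range
#' boundary split the run unless the joining rule for the gap's size range
#' is met (both flanks long enough relative to the gap and combined SNP
#' density sufficient).  Gaps below the lowest boundary never split.
#'
#' @param runs Runs from [detect_runs()].
#' @param calls,positions The sample's call and position vectors.
#' @param join_table Resolved gap-range table (no `NA` boundary).
#' @return A tibble of runs.
#' @export
join_across_gaps <- function(runs, calls, positions, join_table) {
  if (nrow(runs) == 0) return(runs)
  g0 <- join_table$gap_min_bp[1]
  gap_sizes <- diff(positions)
  bigpos <- which(gap_sizes > g0)        # gap k lies between loci k and k+1
  if (length(bigpos) == 0) return(runs)
  cs <- call_cumsums(calls)
  hom <- calls == CALL_HOMREF | calls == CALL_HOMALT
  touched <- vapply(seq_len(nrow(runs)), function(i) {
    any(bigpos >= runs$start_idx[i] & bigpos < runs$end_idx[i])
  }, logical(1))
  if (!any(touched)) return(runs)
  reworked <- purrr::map_dfr(which(touched), function(i) {
    s <- runs$start_idx[i]; e <- runs$end_idx[i]
    big <- bigpos[bigpos >= s & bigpos < e]
    bounds <- c(s - 1L, big, e)
    pieces <- list()
    for (k in seq_len(length(bounds) - 1L)) {
      ix <- (bounds[k] + 1L):bounds[k + 1L]
      homix <- ix[hom[ix]]
      if (length(homix) > 0) pieces <- c(pieces, list(range(homix)))
    }
    if (length(pieces) == 0) return(NULL)
    # left-to-right: try to join each piece to the accumulated segment
    acc <- list(pieces[[1]])
    for (p in pieces[-1]) {
      cur <- acc[[length(acc)]]
      gap <- positions[p[1]] - positions[cur[2]]
      ncalled <- cs$called[p[2] + 1L] - cs$called[cur[1]]
      dens <- ncalled / ((positions[p[2]] - positions[cur[1]] + 1) / 1000)
      left_bp <- positions[cur[2]] - positions[cur[1]] + 1
      right_bp <- positions[p[2]] - positions[p[1]] + 1
      if (gap_join_ok(join_table, gap, left_bp, right_bp, dens)) {
        acc[[length(acc)]] <- c(cur[1], p[2])
      } else {
        acc <- c(acc, list(p))
      }
    }
    tibble(
      start_idx = vapply(acc, function(x) as.integer(x[1]), integer(1)),
      end_idx = vapply(acc, function(x) as.integer(x[2]), integer(1))
    )
  })
  out <- bind_rows(
    runs[!touched, c("start_idx", "end_idx")],
    reworked
  )
  out <- arrange(out, .data$start_idx)
  if (nrow(out) == 0) return(empty_runs())
  run_stats(out, calls)
}

#' Absorb isolated heterozygous 'error' calls between runs
#'
#' Stage 3: two neighbouring runs separated by a single isolated
#' heterozygote (no intervening large gap) are merged when the
#' heterozygote proportion over the flanking run pair -- one het over the
#' pair's non-missing calls -- is within `max_het_proportion`, and the
#' accumulated segment still satisfies the same bound overall.  Denser
#' heterozygote neighbourhoods are left for the scan-ahead stage, which
#' judges them by local heterozygosity.
#'
#' @param runs Runs from [join_across_gaps()].
#' @param calls,positions The sample's vectors.
#' @param params A [detection_params()] (uses `max_het_proportion`).
#' @param g0 Lowest gap boundary: a bridge containing a gap larger than
#'   this is left for the scan-ahead stage.
#' @return A tibble of candidate segments.
#' @export
absorb_het_error <- function(runs, calls, positions, params, g0 = Inf) {
  if (nrow(runs) <= 1) return(runs)
  cs <- call_cumsums(calls)
  cs_big <- c(0L, cumsum(diff(positions) > g0))  # big gaps left of each locus
  rs <- runs$start_idx; re <- runs$end_idx
  run_called <- cs$called[re + 1L] - cs$called[rs]
  n_runs <- length(rs)
  out_s <- integer(n_runs); out_e <- integer(n_runs)
  m <- 1L
  out_s[1L] <- rs[1L]; out_e[1L] <- re[1L]
  for (i in 2:n_runs) {
    s <- out_s[m]
    bridge_het <- cs$het[rs[i]] - cs$het[out_e[m] + 1L]
    bridge_big <- cs_big[rs[i]] - cs_big[out_e[m]] > 0L
    pair_prop <- 1 / (run_called[i - 1L] + run_called[i] + 1)
    acc_het <- cs$het[re[i] + 1L] - cs$het[s]
    acc_called <- cs$called[re[i] + 1L] - cs$called[s]
    if (bridge_het == 1L && !bridge_big &&
        pair_prop <= params$max_het_proportion &&
        acc_het / acc_called <= params$max_het_proportion) {
      out_e[m] <- re[i]
    } else {
      m <- m + 1L
      out_s[m] <- rs[i]; out_e[m] <- re[i]
    }
  }
  run_stats(tibble(start_idx = out_s[1:m], end_idx = out_e[1:m]), calls)
}

#' Scan ahead across heterogeneous gap and heterozygosity structure
#'
#' Stage 4: each candidate segment is greedily extended to the right across
#' following runs.  A candidate end is admissible when the whole extended
#' segment still satisfies `max_het_proportion` and every large gap crossed
#' passes the scan gap rule; the farthest admissible end (maximal SNP
#' count) is taken.  A candidate is rejected when the local heterozygosity
#' at the extension frontier -- over the trailing `min_scan_window` called
#' SNPs of the candidate segment -- exceeds `scan_ahead_het_threshold`,
#' when the extended segment would break `max_het_proportion`, or when a
#' crossed gap fails the rule, so short pockets of clustered error inside
#' an otherwise clean tract are bridged while extension into sustained
#' heterozygosity is refused; the scan terminates once the frontier is
#' locally heterozygous, the overall budget is exhausted, and the scan has
#' ranged past twice the established segment's SNP count without an
#' admissible stop.  Stretches shorter than `min_scan_window` cannot trip
#' the local
#' threshold (a percent-scale proportion needs a real denominator).
#' Extension proceeds left-to-right and never retracts previous joins.
#'
#' @param segs Candidate segments from [absorb_het_error()].
#' @param calls,positions The sample's vectors.
#' @param params A [detection_params()].
#' @param scan_table Resolved gap-range table for this stage.
#' @return A tibble of final segments (still index-based).
#' @export
scan_ahead <- function(segs, calls, positions, params, scan_table) {
  if (nrow(segs) <= 1) return(segs)
  g0 <- scan_table$gap_min_bp[1]
  cs <- call_cumsums(calls)
  gap_sizes <- diff(positions)
  bigpos <- which(gap_sizes > g0)
  cs_big <- c(0L, cumsum(gap_sizes > g0))
  # extension candidates are ends of het-free runs, finer-grained than the
  # stage-3 segments (a partially consumed segment is truncated at the next
  # run start)
  runs <- detect_runs(calls, positions)
  # gap-split boundaries from stage 2 are valid stops/starts too
  run_starts <- sort(unique(c(runs$start_idx, segs$start_idx)))
  run_ends <- sort(unique(c(runs$end_idx, segs$end_idx)))
  # dense-burst walls: loci where the trailing dense_window called SNPs
  # exceed the hard local heterozygosity cap; w25[j] is that window's start
  n <- length(calls)
  dw <- params$dense_window
  w25 <- pmax(1L, findInterval(cs$called[2:(n + 1L)] - dw, cs$called))
  dense_here <- (cs$het[2:(n + 1L)] - cs$het[w25]) >
    params$max_dense_het * (cs$called[2:(n + 1L)] - cs$called[w25])
  dense_here[cs$called[2:(n + 1L)] < dw] <- FALSE
  walls <- which(dense_here)
  wall_starts <- w25[walls]      # nondecreasing with wall position
  max_het <- params$max_het_proportion
  scan_thr <- params$scan_ahead_het_threshold
  min_win <- params$min_scan_window
  cs_het <- cs$het; cs_called <- cs$called
  ss <- segs$start_idx; se <- segs$end_idx
  n_segs <- length(ss)
  i <- 1L
  while (i <= n_segs) {
    s <- ss[i]
    e <- se[i]
    # first dense wall fully beyond the current end blocks everything past it
    k <- findInterval(e, wall_starts) + 1L
    wall <- if (k <= length(walls)) walls[k] else NA_integer_
    cand <- run_ends[run_ends > e]
    if (!is.na(wall)) cand <- cand[cand < wall]
    best <- NA_integer_
    for (je in cand) {
      # local heterozygosity over the trailing min_scan_window called SNPs
      # of the candidate segment; shorter stretches cannot trip the local
      # threshold (a percent-scale proportion needs a real denominator)
      trailing_bad <- FALSE
      tgt <- cs_called[je + 1L] - min_win
      if (tgt >= cs_called[s]) {
        a <- findInterval(tgt, cs_called)
        win_het <- cs_het[je + 1L] - cs_het[a]
        win_called <- cs_called[je + 1L] - cs_called[a]
        trailing_bad <- win_het / win_called > scan_thr
      }
      het <- cs_het[je + 1L] - cs_het[s]
      called <- cs_called[je + 1L] - cs_called[s]
      global_bad <- het / called > max_het
      # terminate when the frontier is locally heterozygous, the overall
      # budget is blown, and the scan has ranged far beyond the
      # established segment -- nothing further is admissible in practice
      if (trailing_bad && global_bad &&
          cs_called[je + 1L] - cs_called[e] >
            2 * (cs_called[e + 1L] - cs_called[s])) break
      if (trailing_bad || global_bad) next
      # every large gap between current end and candidate end must pass
      if (cs_big[je] - cs_big[e] > 0L) {
        big <- bigpos[bigpos >= e & bigpos < je]
        dens <- called / ((positions[je] - positions[s] + 1) / 1000)
        ok <- TRUE
        for (k in big) {
          left_bp <- positions[k] - positions[s] + 1
          right_bp <- positions[je] - positions[k + 1L] + 1
          if (!gap_join_ok(scan_table, gap_sizes[k], left_bp, right_bp, dens)) {
            ok <- FALSE; break
          }
        }
        if (!ok) next
      }
      best <- je
    }
    if (!is.na(best) && best > e) {
      se[i] <- best
      # drop segments swallowed whole; truncate a partially consumed one
      swallowed <- which(seq_len(n_segs) > i & se <= best)
      if (length(swallowed)) {
        keep <- setdiff(seq_len(n_segs), swallowed)
        ss <- ss[keep]; se <- se[keep]; n_segs <- length(ss)
      }
      part <- which(seq_len(n_segs) > i & ss <= best & se > best)
      if (length(part)) {
        nxt <- run_starts[run_starts > best]
        ss[part[1]] <- nxt[1]
      }
      # re-scan from the extended segment before moving on
    } else {
      i <- i + 1L
    }
  }
  run_stats(tibble(start_idx = ss, end_idx = se), calls)
}

#' Detect homozygous segments in a genotype panel
#'
#' Runs the four-stage heuristic -- basic run detection, gap-aware
#' splitting/joining, absorption of isolated heterozygote 'error', and
#' scan-ahead extension -- per sample per chromosome, and annotates each
#' emitted segment with counts and QC flags.  On chromosome X only female
#' samples are used (see [mask_male_chrx()]).  Emitted segments contain at
#' least two homozygous calls and satisfy the heterozygote-proportion
#' invariant.
#'
#' Flags: `high_missing` when the segment no-call rate exceeds
#' `max_nocall_rate`; `low_density` when SNP density is at or below
#' `min_snp_density`; `masked_cnv` when more than half the segment's loci
#' intersect CNV/abnormality intervals of `mask`.
#'
#' @param gm A [genotype_matrix()].
#' @param params A [detection_params()].
#' @param mask Optional [region_mask()] used for the `masked_cnv` flag.
#' @param x_chromosome Chromosome label treated as X.
#' @return A tibble of class `hz_segments`: one row per segment with
#'   coordinates, locus indices (into the chromosome's locus vector),
#'   counts, length and flags.  Attribute `params` stores the parameters.
#' @export
detect_segments <- function(gm, params = detection_params(), mask = NULL,
                            x_chromosome = "X") {
  gm <- mask_male_chrx(gm, x_chromosome)
  chroms <- unique(gm$loci$chromosome)
  cnv_hit <- if (!is.null(mask)) {
    loci_in_mask(gm$loci, mask, c("cnv", "abnormality"))
  } else rep(FALSE, nrow(gm$loci))
  out <- purrr::map_dfr(chroms, function(chr) {
    sel <- which(gm$loci$chromosome == chr)
    if (length(sel) == 0) return(NULL)
    positions <- gm$loci$position_bp[sel]
    g0 <- if (length(positions) >= 3) compute_gap_thresholds(positions) else Inf
    join_tb <- resolve_gap_table(params$gap_width_join_thresholds, g0)
    scan_tb <- resolve_gap_table(params$gap_width_scan_thresholds, g0)
    purrr::map_dfr(seq_len(nrow(gm$samples)), function(si) {
      calls <- gm$calls[si, sel]
      runs <- detect_runs(calls, positions)
      runs <- join_across_gaps(runs, calls, positions, join_tb)
      segs <- absorb_het_error(runs, calls, positions, params, join_tb$gap_min_bp[1])
      segs <- scan_ahead(segs, calls, positions, params, scan_tb)
      segs <- segs[segs$hom_count >= 2, , drop = FALSE]
      if (nrow(segs) == 0) return(NULL)
      n_loci_span <- segs$end_idx - segs$start_idx + 1L
      snp_count <- segs$hom_count + segs$het_count
      length_bp <- positions[segs$end_idx] - positions[segs$start_idx] + 1L
      cs_cnv <- c(0L, cumsum(cnv_hit[sel]))
      cnv_prop <- (cs_cnv[segs$end_idx + 1L] - cs_cnv[segs$start_idx]) /
        n_loci_span
      tibble(
        sample_id = gm$samples$id[si],
        population = gm$samples$population[si],
        chromosome = chr,
        start_bp = positions[segs$start_idx],
        end_bp = positions[segs$end_idx],
        start_idx = segs$start_idx,
        end_idx = segs$end_idx,
        snp_count = snp_count,
        het_count = segs$het_count,
        nocall_count = segs$nocall_count,
        length_bp = as.integer(length_bp),
        high_missing = segs$nocall_count / n_loci_span > params$max_nocall_rate,
        low_density = snp_count / (length_bp / 1000) <= params$min_snp_density,
        masked_cnv = cnv_prop > 0.5
      )
    })
  })
  if (nrow(out) == 0) {
    out <- tibble(
      sample_id = character(), population = character(), chromosome = character(),
      start_bp = integer(), end_bp = integer(), start_idx = integer(),
      end_idx = integer(), snp_count = integer(), het_count = integer(),
      nocall_count = integer(), length_bp = integer(),
      high_missing = logical(), low_density = logical(), masked_cnv = logical()
    )
  }
  class(out) <- c("hz_segments", class(out))
  attr(out, "params") <- params
  out
}
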