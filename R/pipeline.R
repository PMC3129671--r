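#' Run the full contiguous-homozygosity pipeline
#'
#' Orchestrates the standard analysis on one genotype panel: segment
#' detection, annotation (HPS, MAD score, founder-haplotype frequency),
#' per-chromosome centimorgan ISLMs with autozygosity capping, per
#' population the percentile-extent matrix, ext_AUC track and ranks, peak
#' detection / merging / outlier flagging / region merging with haplotype
#' parameters, candidate fixed areas, pairwise per-locus theta, and
#' (optionally) the two-group Cramer-von Mises scan.  All stages are
#' deterministic given the inputs.  When `out_dir` is given every result
#' table is written as TSV together with a JSON manifest of parameters and
#' file checksums, so a rerun can be verified byte-identically.
#'
#' @param gm A [genotype_matrix()] (already QC'd, or use `maf_min`).
#' @param panel Optional [phased_panel()] (enables founder-haplotype
#'   frequencies and `freq_hap_max`).
#' @param arm_rates Arm recombination-rate table; when `NULL`, a flat
#'   1 cM/Mb map over the observed positions is assumed.
#' @param params [detection_params()].
#' @param mask Optional [region_mask()].
#' @param maf_min MAF filter applied first (`NULL` to skip).
#' @param hps_max `HPS_ex` filter for the ISLM (default 0.01).
#' @param mad_threshold Autozygosity MAD threshold (default 10).
#' @param aha Optional list `list(pop_a =, pop_b =, n_perm =)` enabling the
#'   Cramer-von Mises scan between two populations.
#' @param seed Seed for the permutation stage.
#' @param out_dir Optional output directory.
#' @return A list of class `hz_pipeline`: `segments`, `misl`, `islm`
#'   (per chromosome), `pemat` and `tracks` (per population), `peaks`,
#'   `regions`, `fixed_areas`, `fst`, `aha`, `manifest`.
#' @export
run_pipeline <- function(gm, panel = NULL, arm_rates = NULL,
                         params = detection_params(), mask = NULL,
                         maf_min = NULL, hps_max = 0.01, mad_threshold = 10,
                         aha = NULL, seed = 1L, out_dir = NULL) {
  if (!is.null(maf_min)) gm <- filter_maf(gm, maf_min)
  if (!is.null(mask)) gm <- apply_region_mask(gm, mask)
  if (is.null(arm_rates)) {
    arm_rates <- purrr::map_dfr(unique(gm$loci$chromosome), function(chr) {
      pos <- gm$loci$position_bp[gm$loci$chromosome == chr]
      tibble(chromosome = chr, arm = "p", start_bp = min(pos),
             end_bp = max(pos), cm_per_mb = 1)
    })
  }
  segments <- detect_segments(gm, params, mask = mask)
  segments <- annotate_segments(segments, gm, panel = panel,
                                mad_threshold = mad_threshold)
  segments$length_cm <- segments_cm(segments, arm_rates)
  misl <- compute_misl(segments)
  pops <- unique(gm$samples$population)
  chroms <- unique(gm$loci$chromosome)
  islm <- lapply(setNames(chroms, chroms), function(chr) {
    m <- build_islm(segments, gm, chromosome = chr, units = "cm",
                    arm_rates = arm_rates, filter_hps = hps_max)
    mask_islm_autozygous(m, mad_threshold)
  })
  pemat <- lapply(setNames(pops, pops), function(p) {
    lapply(islm, pe_mat, population = p)
  })
  tracks <- purrr::map_dfr(pops, function(p) {
    purrr::map_dfr(islm, ext_auc, population = p)
  }) |> ext_auc_rank()
  peaks <- purrr::map_dfr(pops, function(p) {
    purrr::map_dfr(chroms, function(chr) {
      tr <- tracks[tracks$population == p & tracks$chromosome == chr, ]
      if (nrow(tr) < 34) return(NULL)
      sm <- smooth_track(tr$ext_auc, tr$position_bp)
      pk <- detect_peaks(sm) |> merge_peaks() |> flag_outlier_peaks()
      if (nrow(pk) == 0) return(NULL)
      pk$population <- p
      pk$chromosome <- chr
      hp <- purrr::map_dfr(seq_len(nrow(pk)), function(i) {
        peak_haplotype_params(pk[i, ], pemat[[p]][[chr]],
                              segments = if (!is.null(panel)) segments)
      })
      bind_rows(mutate(pk, !!!hp))
    })
  })
  regions <- if (nrow(peaks) > 0) {
    peaks |>
      group_by(.data$population, .data$chromosome) |>
      dplyr::group_modify(function(d, key) merge_outlier_regions(d)) |>
      ungroup()
  } else tibble()
  fixed_areas <- detect_fixed_areas(
    unlist(pemat, recursive = FALSE, use.names = FALSE)
  )
  fst <- if (length(pops) >= 2) {
    pairs <- utils::combn(pops, 2, simplify = FALSE)
    purrr::map_dfr(pairs, function(pr) {
      mutate(fst_scan(gm, pr[1], pr[2]), pop_a = pr[1], pop_b = pr[2])
    })
  } else tibble()
  aha_res <- NULL
  if (!is.null(aha)) {
    aha_res <- purrr::map_dfr(chroms, function(chr) {
      m <- islm[[chr]]
      sub <- function(p) {
        rows <- m$samples$population == p
        out <- m
        out$values <- m$values[rows, , drop = FALSE]
        out$samples <- m$samples[rows, ]
        out
      }
      mutate(cvm_scan(sub(aha$pop_a), sub(aha$pop_b),
                      n_perm = aha$n_perm %||% 0, seed = seed),
             chromosome = chr)
    })
  }
  out <- structure(list(
    segments = segments, misl = misl, islm = islm, pemat = pemat,
    tracks = tracks, peaks = peaks, regions = regions,
    fixed_areas = fixed_areas, fst = fst, aha = aha_res,
    manifest = list(
      package_version = as.character(utils::packageVersion("hzkit")),
      seed = seed, hps_max = hps_max, mad_threshold = mad_threshold,
      params = unclass(params)
    )
  ), class = "hz_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' @export
print.hz_pipeline <- function(x, ...) {
  cat(sprintf(
    "<hz_pipeline> %d segments, %d peaks (%d outliers), %d fixed-area runs\n",
    nrow(x$segments), nrow(x$peaks),
    if (nrow(x$peaks)) sum(x$peaks$outlier) else 0L,
    nrow(x$fixed_areas)
  ))
  invisible(x)
}

#' @export
glance.hz_pipeline <- function(x, ...) {
  tibble(
    n_segments = nrow(x$segments),
    n_peaks = nrow(x$peaks),
    n_outlier_peaks = if (nrow(x$peaks)) sum(x$peaks$outlier) else 0L,
    n_peak_regions = nrow(x$regions),
    n_fixed_runs = nrow(x$fixed_areas),
    n_candidate_fixed = if (nrow(x$fixed_areas)) sum(x$fixed_areas$candidate) else 0L
  )
}

# Write every tabular result as TSV plus a JSON manifest with checksums.
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(tb, name) {
    if (is.null(tb) || nrow(tb) == 0) return(NULL)
    tb <- dplyr::select(tb, -dplyr::where(is.list))
    path <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(tb, path, progress = FALSE)
    path
  }
  paths <- c(
    wr(res$segments, "segments"),
    wr(res$misl$misl_chr, "misl"),
    wr(res$tracks, "ext_auc"),
    wr(res$peaks, "peaks"),
    wr(res$regions, "peak_regions"),
    wr(res$fixed_areas, "fixed_areas"),
    wr(res$fst, "fst"),
    wr(res$aha, "aha")
  )
  manifest <- res$manifest
  manifest$files <- as.list(tools::md5sum(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
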