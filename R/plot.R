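#' Plot homozygous segments as a per-sample track
#'
#' One horizontal line per segment, samples along the y axis, colour-coded
#' by status flag (putatively autozygous, low density, high missingness,
#' CNV-masked).
#'
#' @param segments A segment tibble.
#' @param chromosome Optional chromosome to restrict to.
#' @return A ggplot object.
#' @export
plot_segments <- function(segments, chromosome = NULL) {
  if (!is.null(chromosome)) {
    segments <- segments[segments$chromosome == chromosome, ]
  }
  status <- rep("segment", nrow(segments))
  if ("high_missing" %in% names(segments)) status[segments$high_missing] <- "high missing"
  if ("low_density" %in% names(segments)) status[segments$low_density] <- "low density"
  if ("masked_cnv" %in% names(segments)) status[segments$masked_cnv] <- "CNV-masked"
  if ("putative_autozygous" %in% names(segments)) {
    status[segments$putative_autozygous] <- "putative autozygous"
  }
  segments$status <- status
  ggplot2::ggplot(segments, ggplot2::aes(
    x = .data$start_bp / 1e6, xend = .data$end_bp / 1e6,
    y = .data$sample_id, yend = .data$sample_id, colour = .data$status
  )) +
    ggplot2::geom_segment(linewidth = 1.2) +
    ggplot2::scale_colour_manual(values = c(
      "segment" = "firebrick", "putative autozygous" = "forestgreen",
      "low density" = "goldenrod", "high missing" = "steelblue",
      "CNV-masked" = "orange"
    )) +
    ggplot2::facet_grid(.data$population ~ ., scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot a percentile-extent matrix as a grayscale image with ext_AUC
#'
#' The matrix values are plotted as grayscale tiles (capped at the maximum
#' of the 90th percentile column, darker = longer extent), optionally with
#' the smoothed ext_AUC track superimposed.
#'
#' @param pemat An `hz_pemat`.
#' @param track Optional ext_AUC track for the same chromosome/population.
#' @return A ggplot object.
#' @export
plot_pe_heatmap <- function(pemat, track = NULL) {
  df <- tidy(pemat)
  cap <- max(pemat$values[, 91], na.rm = TRUE)
  if (!is.finite(cap) || cap <= 0) cap <- max(df$value, na.rm = TRUE)
  df$value_capped <- pmin(df$value, cap)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$position_bp / 1e6, y = .data$percentile,
    fill = .data$value_capped
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, cap)) +
    ggplot2::labs(x = "position (Mb)", y = "percentile",
                  fill = paste0("extent (", pemat$units, ")"),
                  title = pemat$population) +
    ggplot2::theme_minimal()
  if (!is.null(track)) {
    tr <- track[track$population == pemat$population, ]
    scale <- 100 / max(tr$ext_auc, na.rm = TRUE)
    p <- p + ggplot2::geom_line(
      data = tr, inherit.aes = FALSE, colour = "red",
      ggplot2::aes(x = .data$position_bp / 1e6, y = .data$ext_auc * scale)
    )
  }
  p
}

#' Plot an ext_AUC track with peak annotations
#'
#' @param track A (ranked) ext_AUC track.
#' @param peaks Optional peak tibble; outlier apexes are marked.
#' @return A ggplot object.
#' @export
plot_ext_auc <- function(track, peaks = NULL) {
  p <- ggplot2::ggplot(track, ggplot2::aes(
    x = .data$position_bp / 1e6, y = .data$ext_auc, colour = .data$population
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (Mb)", y = "ext_AUC", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0 && any(peaks$outlier)) {
    op <- peaks[peaks$outlier, ]
    p <- p + ggplot2::geom_point(
      data = op, inherit.aes = FALSE, shape = 17, colour = "black",
      ggplot2::aes(x = .data$apex_bp / 1e6, y = .data$height)
    )
  }
  p
}

#' Plot an omega-squared scan track
#'
#' @param scan Output of [cvm_scan()].
#' @param alpha Significance level marking permutation-tested loci.
#' @return A ggplot object.
#' @export
plot_omega2 <- function(scan, alpha = 0.05) {
  scan$significant <- !is.na(scan$asl) & scan$asl <= alpha
  ggplot2::ggplot(scan, ggplot2::aes(
    x = .data$position_bp / 1e6, y = .data$omega2
  )) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = scan[scan$significant, ], colour = "red", size = 1) +
    ggplot2::labs(x = "position (Mb)", y = expression(omega^2)) +
    ggplot2::theme_minimal()
}

#' Plot phased haplotypes ordered by hierarchical clustering
#'
#' Haplotype rows are ordered by average-linkage agglomerative clustering
#' of their allele vectors (manhattan distance), one panel per population,
#' so shared extended haplotypes appear as blocks.
#'
#' @param panel A [phased_panel()].
#' @param locus_index Columns (loci) to plot.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A ggplot object.
#' @export
plot_haplotypes <- function(panel, locus_index, linkage = "average") {
  hap <- panel$haplotypes[, locus_index, drop = FALSE]
  ord <- unlist(lapply(unique(panel$population), function(p) {
    rows <- which(panel$population == p)
    if (length(rows) < 3) return(rows)
    d <- stats::dist(hap[rows, , drop = FALSE], method = "manhattan")
    rows[stats::hclust(d, method = linkage)$order]
  }))
  df <- tibble(
    row = rep(seq_along(ord), times = length(locus_index)),
    population = rep(panel$population[ord], times = length(locus_index)),
    locus = rep(seq_along(locus_index), each = length(ord)),
    allele = factor(as.integer(hap[ord, , drop = FALSE]))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$locus, y = .data$row,
                                   fill = .data$allele)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c("0" = "navy", "1" = "gold"),
                               na.value = "grey80") +
    ggplot2::facet_grid(.data$population ~ ., scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "locus", y = NULL, fill = "allele") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @rdname plot_ext_auc
#' @param object An `hz_exttrack`.
#' @param ... Unused.
#' @export
autoplot.hz_exttrack <- function(object, ...) plot_ext_auc(object)

#' @rdname plot_pe_heatmap
#' @param object An `hz_pemat`.
#' @param ... Unused.
#' @export
autoplot.hz_pemat <- function(object, ...) plot_pe_heatmap(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
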