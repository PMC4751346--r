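#' Pairwise linkage disequilibrium within a chromosome
#'
#' Composite LD on unphased additive codes: `r2` is the squared Pearson
#' correlation between the -1/0/1 (or imputed) code vectors of every pair of
#' mapped markers on the chromosome; distance is the absolute map-position
#' difference in centimorgans.  Monomorphic markers carry no LD information
#' and are excluded (their count is recorded).
#'
#' @param g a [genotype_matrix()] without missing values (impute first).
#' @param map a `marker_map` (see [marker_map()]).
#' @param chromosome chromosome number to analyse.
#' @return A list of class `ld_decay`: `chromosome`, `pairs` (data.frame
#'   `marker_i`, `marker_j`, `distance_cM`, `r2`), `adjacent_mean` (mean r2
#'   over consecutive mapped marker pairs), `mean_adjacent_spacing` (cM) and
#'   `n_monomorphic` (markers excluded).
#' @export
pairwise_ld <- function(g, map, chromosome) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g)) stop("genotype matrix contains missing values; impute first")
  map <- marker_map(as.data.frame(map), n_chromosomes = max(map$chromosome))
  sub <- map[map$chromosome == chromosome, , drop = FALSE]
  sub <- sub[sub$marker_id %in% colnames(g), , drop = FALSE]
  if (nrow(sub) < 2L)
    stop("need >= 2 mapped markers on chromosome ", chromosome)
  codes <- unclass(g)[, sub$marker_id, drop = FALSE]
  poly <- apply(codes, 2L, stats::sd) > 0
  n_mono <- sum(!poly)
  sub <- sub[poly, , drop = FALSE]
  codes <- codes[, poly, drop = FALSE]
  if (nrow(sub) < 2L)
    stop("fewer than 2 polymorphic mapped markers on chromosome ", chromosome)
  r2 <- stats::cor(codes)^2
  m <- nrow(sub)
  ut <- which(upper.tri(r2), arr.ind = TRUE)
  pairs <- data.frame(marker_i = sub$marker_id[ut[, 1L]],
                      marker_j = sub$marker_id[ut[, 2L]],
                      distance_cM = abs(sub$position_cM[ut[, 2L]] -
                                          sub$position_cM[ut[, 1L]]),
                      r2 = r2[ut], stringsAsFactors = FALSE)
  adj <- cbind(seq_len(m - 1L), seq_len(m - 1L) + 1L)
  structure(list(chromosome = chromosome, pairs = pairs,
                 adjacent_mean = mean(r2[adj]),
                 mean_adjacent_spacing = mean(diff(sub$position_cM)),
                 n_monomorphic = n_mono),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat(sprintf("LD decay, chromosome %s: %d marker pairs\n",
              format(x$chromosome), nrow(x$pairs)))
  cat(sprintf("  adjacent-pair mean r2 = %.3f at mean spacing %.3f cM (%d monomorphic excluded)\n",
              x$adjacent_mean, x$mean_adjacent_spacing, x$n_monomorphic))
  invisible(x)
}

#' LD decay curve: binned means and a cubic smoothing spline
#'
#' Bins the (distance, r2) pairs of an [pairwise_ld()] result by map
#' distance and superimposes a cubic smoothing spline whose smoothing
#' parameter is chosen by generalized cross-validation.  Empty bins are
#' absent from the output (not reported as zero).
#'
#' @param decay an `ld_decay` object (>= 10 pairs).
#' @param bin_width bin width in centimorgans.
#' @param grid_points number of points at which the spline is evaluated.
#' @return A list of class `ld_curve`: `bins` (data.frame `mid`, `mean_r2`,
#'   `n`), `grid` (data.frame `distance_cM`, `r2_fit`; `NULL` when all
#'   pairs share one distance) and the fitted `spline` object.
#' @export
ld_decay_curve <- function(decay, bin_width = 5, grid_points = 200L) {
  stopifnot(inherits(decay, "ld_decay"))
  d <- decay$pairs$distance_cM
  r2 <- decay$pairs$r2
  if (length(d) < 10L) stop("need >= 10 pairs for a decay curve")
  br <- seq(0, max(d) + bin_width, by = bin_width)
  bin <- cut(d, br, include.lowest = TRUE)
  keep <- !is.na(bin) & tabulate(bin, nbins = nlevels(bin))[as.integer(bin)] > 0L
  agg <- tapply(r2, bin, mean)
  cnt <- tabulate(bin, nbins = nlevels(bin))
  mids <- (br[-1L] + br[-length(br)]) / 2
  bins <- data.frame(mid = mids[cnt > 0L], mean_r2 = as.numeric(agg[cnt > 0L]),
                     n = cnt[cnt > 0L])
  if (length(unique(d)) < 4L) {
    return(structure(list(bins = bins, grid = NULL, spline = NULL),
                     class = "ld_curve"))
  }
  sp <- stats::smooth.spline(d, r2, cv = FALSE)  # GCV-chosen smoothing
  gx <- seq(min(d), max(d), length.out = grid_points)
  structure(list(bins = bins,
                 grid = data.frame(distance_cM = gx,
                                   r2_fit = stats::predict(sp, gx)$y),
                 spline = sp),
            class = "ld_curve")
}

#' @export
print.ld_curve <- function(x, ...) {
  cat("LD decay curve:", nrow(x$bins), "non-empty bins",
      if (is.null(x$spline)) "(spline skipped: degenerate distances)", "\n")
  invisible(x)
}

#' Plot LD against map distance with the smoothed decay curve
#' @param x an `ld_curve`.
#' @param decay optionally, the `ld_decay` object to show raw pairs.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ld_curve <- function(x, decay = NULL, ...) {
  if (!is.null(decay)) {
    graphics::plot(decay$pairs$distance_cM, decay$pairs$r2, pch = ".",
                   col = "grey50", xlab = "distance (cM)",
                   ylab = expression(r^2), ...)
    graphics::points(x$bins$mid, x$bins$mean_r2, pch = 19)
  } else {
    graphics::plot(x$bins$mid, x$bins$mean_r2, pch = 19,
                   xlab = "distance (cM)", ylab = expression(r^2), ...)
  }
  if (!is.null(x$grid))
    graphics::lines(x$grid$distance_cM, x$grid$r2_fit, col = "red", lwd = 2)
  invisible(x)
}

#' Write per-chromosome LD tables and a summary
#'
#' Writes `ld_chr<k>.tsv` (marker_i, marker_j, distance_cM, r2) per
#' chromosome plus `ld_summary.tsv` (chromosome, n_pairs, adjacent_mean,
#' mean_adjacent_spacing_cM, n_monomorphic), and optionally a simple r2
#' heatmap PNG per chromosome.
#'
#' @param g,map as in [pairwise_ld()].
#' @param dir output directory.
#' @param heatmap logical; also export `ld_heatmap_chr<k>.png`.
#' @return The summary data.frame, invisibly.
#' @export
write_ld_tables <- function(g, map, dir, heatmap = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chroms <- sort(unique(map$chromosome[map$marker_id %in% colnames(g)]))
  summary <- lapply(chroms, function(chr) {
    ld <- pairwise_ld(g, map, chr)
    utils::write.table(ld$pairs, file.path(dir, sprintf("ld_chr%s.tsv", chr)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (heatmap) {
      ord <- ld$pairs
      ids <- unique(c(ord$marker_i, ord$marker_j))
      m <- diag(1, length(ids))
      dimnames(m) <- list(ids, ids)
      m[cbind(ord$marker_i, ord$marker_j)] <- ord$r2
      m[cbind(ord$marker_j, ord$marker_i)] <- ord$r2
      grDevices::png(file.path(dir, sprintf("ld_heatmap_chr%s.png", chr)),
                     width = 600, height = 600)
      graphics::image(m, axes = FALSE, main = sprintf("chromosome %s", chr),
                      col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
      grDevices::dev.off()
    }
    data.frame(chromosome = chr, n_pairs = nrow(ld$pairs),
               adjacent_mean = ld$adjacent_mean,
               mean_adjacent_spacing_cM = ld$mean_adjacent_spacing,
               n_monomorphic = ld$n_monomorphic)
  })
  summary <- do.call(rbind, summary)
  utils::write.table(summary, file.path(dir, "ld_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(summary)
}
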