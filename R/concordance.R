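# Platform-comparison analytics: KDE modality classification of methylation
# distributions, array-vs-RRBS correlation per cell, and the pairwise
# cross-cell correlation matrix on shared RRBS sites.

#' Classify the modality of a methylation distribution by kernel density
#'
#' A Gaussian KDE (Silverman bandwidth by default) is evaluated on a grid
#' spanning [-0.05, 1.05] and truncated to [0, 1] to avoid boundary-artifact
#' modes at 0/1; modes are local maxima whose topographic prominence is at
#' least `prominence_min` of the global peak height. Methylation landscapes
#' classify as unimodal, bimodal or trimodal this way.
#'
#' @param values methylation proportions in [0, 1].
#' @param bandwidth optional scalar bandwidth override (default Silverman).
#' @param prominence_min minimal prominence as a fraction of the global
#'   maximum.
#' @param min_n minimum number of values required.
#' @return list of class "modality_call": n_modes, mode_locations (sorted),
#'   bandwidth, grid (x, y) for plotting.
#' @export
kde_modality <- function(values, bandwidth = NULL, prominence_min = 0.05,
                         min_n = 100L) {
  values <- values[!is.na(values)]
  if (length(values) < min_n) {
    stop(sprintf("insufficient data: %d values, need >= %d",
                 length(values), min_n))
  }
  if (any(values < 0 | values > 1)) stop("values must lie in [0, 1]")
  if (stats::sd(values) == 0) {
    stop("insufficient variance: values are constant, bandwidth undefined")
  }
  bw <- if (is.null(bandwidth)) stats::bw.nrd0(values) else bandwidth
  # grid spacing chosen so that ~512 points land inside [0, 1]
  d <- stats::density(values, bw = bw, from = -0.05, to = 1.05, n = 563)
  keep <- d$x >= 0 & d$x <= 1
  x <- d$x[keep]
  y <- d$y[keep]
  peaks <- find_modes(x, y, prominence_min)
  structure(list(n_modes = length(peaks), mode_locations = sort(x[peaks]),
                 bandwidth = bw, grid = data.frame(x = x, y = y)),
            class = "modality_call")
}

# topographic prominence on a 1-D grid: for each local maximum, walk out on
# both sides to the nearest higher ground; the key saddle is the higher of
# the two path minima (or the global minimum side if no higher ground).
find_modes <- function(x, y, prominence_min) {
  n <- length(y)
  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  if (y[1] > y[2]) is_max <- c(1L, is_max)
  if (y[n] > y[n - 1]) is_max <- c(is_max, n)
  if (length(is_max) == 0) is_max <- which.max(y)
  prom <- vapply(is_max, function(i) {
    h <- y[i]
    side_saddle <- function(idx_range) {
      if (length(idx_range) == 0) return(NA_real_)
      higher <- idx_range[y[idx_range] > h]
      if (length(higher) == 0) return(NA_real_)
      stop_at <- if (idx_range[1] < i) max(higher) else min(higher)
      path <- if (idx_range[1] < i) seq(stop_at, i) else seq(i, stop_at)
      min(y[path])
    }
    left <- side_saddle(seq_len(i - 1))
    right <- side_saddle(if (i < n) seq(i + 1L, n) else integer(0))
    saddles <- c(left, right)
    if (all(is.na(saddles))) h - min(y) else h - max(saddles, na.rm = TRUE)
  }, numeric(1))
  is_max[prom >= prominence_min * max(y)]
}

#' Correlate RRBS methylation with 450K-style probe betas for one cell
#'
#' Joins on exact (chrom, pos), keeps RRBS sites passing the coverage filter
#' (the read-depth >= 10 rule), and returns the Pearson correlation between
#' the RRBS methylation proportion and the array beta.
#'
#' @param rrbs CpG record table.
#' @param probes data.frame with columns probe_id, chrom, pos, beta
#'   (0-based pos, beta in [0, 1]).
#' @param min_coverage RRBS coverage filter.
#' @return list(r, n_shared).
#' @export
platform_correlation <- function(rrbs, probes, min_coverage = 10L) {
  stopifnot(all(c("chrom", "pos", "beta") %in% names(probes)))
  if (any(probes$beta < 0 | probes$beta > 1)) stop("beta values must be in [0, 1]")
  r <- rrbs[rrbs$coverage >= min_coverage, , drop = FALSE]
  m <- merge(
    data.frame(chrom = r$chrom, pos = r$pos,
               prop = r$meth_count / r$coverage),
    probes[, c("chrom", "pos", "beta")],
    by = c("chrom", "pos")
  )
  if (nrow(m) < 3) {
    stop(sprintf("undefined correlation: only %d shared sites (need >= 3)",
                 nrow(m)))
  }
  list(r = stats::cor(m$prop, m$beta), n_shared = nrow(m))
}

#' Pairwise Pearson correlation matrix across cell-type methylomes
#'
#' For each pair of cells the correlation is computed on the intersection of
#' sites passing the coverage filter in both; a pair with fewer than 3 shared
#' sites is flagged missing (NA), never fabricated.
#'
#' @param methylomes named list of CpG record tables (>= 2 cells).
#' @param min_coverage coverage filter applied per cell.
#' @return list of class "correlation_matrix": `values` (symmetric Pearson r
#'   matrix, unit diagonal) and `n_shared` (shared-site counts).
#' @export
pairwise_cell_matrix <- function(methylomes, min_coverage = 10L) {
  cells <- names(methylomes)
  if (length(cells) < 2) stop("need >= 2 cell types")
  props <- lapply(methylomes, function(m) {
    m <- m[m$coverage >= min_coverage, , drop = FALSE]
    data.frame(chrom = m$chrom, pos = m$pos,
               prop = m$meth_count / m$coverage)
  })
  k <- length(cells)
  r <- matrix(1, k, k, dimnames = list(cells, cells))
  ns <- matrix(0L, k, k, dimnames = list(cells, cells))
  for (i in seq_len(k)) ns[i, i] <- nrow(props[[i]])
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      m <- merge(props[[i]], props[[j]], by = c("chrom", "pos"))
      ns[i, j] <- ns[j, i] <- nrow(m)
      r[i, j] <- r[j, i] <-
        if (nrow(m) < 3) NA_real_ else stats::cor(m$prop.x, m$prop.y)
    }
  }
  structure(list(labels = cells, values = r, n_shared = ns),
            class = "correlation_matrix")
}
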