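# TF-methylation interplay: promoter methylation of peak-bound genes is
# pooled over all (cell, TF) combinations into a Beta background model; each
# combination is then Kolmogorov-Smirnov-tested against the background CDF,
# BH-corrected, and classified highly-differentiated / lowly-differentiated
# / null (too little data).

#' Extract promoter methylation at TF-bound windows
#'
#' Returns the methylation proportions of CpGs (passing the coverage filter)
#' lying inside TSS +/- 1,000 bp windows that overlap at least one peak
#' (any-overlap rule, a single shared base counts).
#'
#' @param methylome CpG record table.
#' @param peaks interval data.frame of TF peaks.
#' @param windows promoter-window interval data.frame (see
#'   [promoter_windows()]).
#' @param min_coverage read-depth filter.
#' @return numeric vector of methylation proportions (possibly empty).
#' @export
extract_tf_methylation <- function(methylome, peaks, windows,
                                   min_coverage = 10L) {
  if (is.null(peaks) || nrow(peaks) == 0 || nrow(windows) == 0) {
    return(numeric(0))
  }
  bound <- IRanges::overlapsAny(as_granges(windows), as_granges(peaks),
                                ignore.strand = TRUE)
  win <- windows[bound, , drop = FALSE]
  m <- methylome[methylome$coverage >= min_coverage, , drop = FALSE]
  inside <- sites_in_intervals(m, win)
  m$meth_count[inside] / m$coverage[inside]
}

#' Fit the Beta background model of promoter methylation
#'
#' Method of moments by default: with sample mean m and variance v,
#' k = m(1 - m)/v - 1, alpha = m k, beta = (1 - m) k. Values are clamped to
#' [epsilon, 1 - epsilon] first so boundary values never break the fit.
#' `method = "mle"` refines the moment estimate by maximum likelihood.
#'
#' @param values aggregated methylation proportions across all (cell, TF)
#'   combinations.
#' @param method "moments" or "mle".
#' @param epsilon clamping margin.
#' @param min_n minimum number of values required.
#' @return list of class "background_model": alpha, beta, n_points,
#'   fit_method.
#' @export
fit_background <- function(values, method = c("moments", "mle"),
                           epsilon = 1e-6, min_n = 100L) {
  method <- match.arg(method)
  values <- clamp(values[!is.na(values)], epsilon, 1 - epsilon)
  if (length(values) < min_n) {
    stop(sprintf("need >= %d values to fit the background (have %d)",
                 min_n, length(values)))
  }
  m <- mean(values)
  v <- stats::var(values)
  if (v >= m * (1 - m)) {
    stop("sample variance >= m(1-m): over-dispersed beyond Beta support; ",
         "review clamping or use method = 'mle' on cleaned data")
  }
  k <- m * (1 - m) / v - 1
  alpha <- m * k
  beta <- (1 - m) * k
  if (method == "mle") {
    nll <- function(par) {
      -sum(stats::dbeta(values, exp(par[1]), exp(par[2]), log = TRUE))
    }
    opt <- stats::optim(log(c(alpha, beta)), nll, method = "BFGS")
    alpha <- exp(opt$par[1])
    beta <- exp(opt$par[2])
  }
  structure(list(alpha = alpha, beta = beta, n_points = length(values),
                 fit_method = method),
            class = "background_model")
}

#' One-sample Kolmogorov-Smirnov test against the Beta background
#'
#' D is the supremum over sample points of |ECDF - Beta CDF| (both one-sided
#' gaps), with the p-value from the asymptotic Kolmogorov distribution;
#' delegates to `stats::ks.test(..., exact = FALSE)`. Values are clamped by
#' `epsilon` before CDF evaluation.
#'
#' @param values methylation proportions (n >= 1).
#' @param background a [fit_background()] model.
#' @param epsilon clamping margin.
#' @return list(statistic, p_value).
#' @export
ks_test_against_background <- function(values, background, epsilon = 1e-6) {
  if (length(values) == 0) stop("empty value vector")
  if (any(values < 0 | values > 1)) stop("values must lie in [0, 1]")
  values <- clamp(values, epsilon, 1 - epsilon)
  kt <- suppressWarnings(stats::ks.test(
    values, stats::pbeta, background$alpha, background$beta, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Classify TF-methylation interplay across a (cell, TF) grid
#'
#' Combinations with fewer than `min_sites` CpG values (or absent entirely)
#' are "null"; the rest are K-S-tested against the background, BH-corrected
#' across tested combinations only, and classified
#' "highly-differentiated" (adjusted p <= alpha) or "lowly-differentiated".
#' If no background is supplied it is fitted on the aggregate of the same
#' combination set.
#'
#' @param values_by_combo named list "<cell>|<tf>" -> methylation
#'   proportions; entries may be NULL/empty (no-data combos).
#' @param background optional [fit_background()] model.
#' @param min_sites minimum CpGs for a combo to be testable.
#' @param alpha adjusted-p threshold for the highly-differentiated class.
#' @return data.frame of class "tf_methylation_calls": cell, tf, n_cpgs, D,
#'   p, adj_p, class; the fitted background is attached as attribute
#'   "background".
#' @export
classify_interplay <- function(values_by_combo, background = NULL,
                               min_sites = 50L, alpha = 0.05) {
  keys <- names(values_by_combo)
  if (is.null(keys)) stop("values_by_combo must be a named list")
  parts <- strsplit(keys, "|", fixed = TRUE)
  cells <- vapply(parts, `[`, character(1), 1L)
  tfs <- vapply(parts, function(x) paste(x[-1], collapse = "|"), character(1))
  n_cpgs <- vapply(values_by_combo, length, integer(1))
  if (is.null(background)) {
    background <- fit_background(unlist(values_by_combo, use.names = FALSE))
  }
  testable <- n_cpgs >= min_sites
  D <- rep(NA_real_, length(keys))
  p <- rep(NA_real_, length(keys))
  for (i in which(testable)) {
    kt <- ks_test_against_background(values_by_combo[[i]], background)
    D[i] <- kt$statistic
    p[i] <- kt$p_value
  }
  adj_p <- rep(NA_real_, length(keys))
  adj_p[testable] <- benjamini_hochberg(p[testable])
  class <- ifelse(!testable, "null",
                  ifelse(adj_p <= alpha, "highly-differentiated",
                         "lowly-differentiated"))
  out <- data.frame(cell = cells, tf = tfs, n_cpgs = n_cpgs, D = D, p = p,
                    adj_p = adj_p, class = class, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "background") <- background
  class(out) <- c("tf_methylation_calls", "data.frame")
  out
}

#' Tabulate interplay classes as a cells x TFs grid
#' @param calls a [classify_interplay()] result.
#' @return character matrix, rows = cells, columns = TFs.
#' @export
interplay_class_grid <- function(calls) {
  cells <- sort(unique(calls$cell))
  tfs <- sort(unique(calls$tf))
  g <- matrix("null", length(cells), length(tfs),
              dimnames = list(cells, tfs))
  for (i in seq_len(nrow(calls))) {
    g[calls$cell[i], calls$tf[i]] <- calls$class[i]
  }
  g
}
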