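# DMC/DMR calling between a reference cell type and a comparator, and
# cell-type-specific DMR discovery by set deduction against the union of all
# other cell types' DMR sets.

#' Vectorized two-sided Fisher exact test for 2x2 methylation tables
#'
#' For each site the table is [(meth, unmeth)_ref; (meth, unmeth)_other].
#' The two-sided p-value sums, over the fixed-margin hypergeometric support,
#' the probabilities of all tables no more likely than the observed one
#' (relative-likelihood rule with tolerance 1e-7, the same convention as
#' stats::fisher.test). Computation is memoised over unique tables.
#'
#' @param meth1,cov1 methylated count and coverage in sample 1.
#' @param meth2,cov2 methylated count and coverage in sample 2.
#' @return numeric vector of p-values.
#' @export
fisher_test_counts <- function(meth1, cov1, meth2, cov2) {
  stopifnot(length(meth1) == length(cov1), length(meth1) == length(meth2),
            length(meth1) == length(cov2))
  if (length(meth1) == 0) return(numeric(0))
  if (any(meth1 > cov1) || any(meth2 > cov2) || any(meth1 < 0) || any(meth2 < 0)) {
    stop("counts must satisfy 0 <= meth <= coverage")
  }
  key <- paste(meth1, cov1, meth2, cov2, sep = ":")
  uk <- !duplicated(key)
  p_one <- function(m1, c1, m2, c2) {
    k <- m1 + m2
    lo <- max(0L, k - c2)
    hi <- min(c1, k)
    supp <- seq.int(lo, hi)
    d <- dhyper(supp, c1, c2, k)
    d0 <- d[m1 - lo + 1L]
    min(1, sum(d[d <= d0 * (1 + 1e-7)]))
  }
  pu <- mapply(p_one, meth1[uk], cov1[uk], meth2[uk], cov2[uk])
  unname(pu[match(key, key[uk])])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, the multiple-testing
#' correction used throughout the pipeline (per-site DMC q-values, DMR
#' window q-values, TF-interplay adjusted p).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted q-values, monotone, capped at 1.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# join two methylomes on (chrom, pos), both passing the coverage filter
shared_sites <- function(ref, other, min_coverage) {
  r <- ref[ref$coverage >= min_coverage, c("chrom", "pos", "coverage", "meth_count")]
  o <- other[other$coverage >= min_coverage, c("chrom", "pos", "coverage", "meth_count")]
  m <- merge(r, o, by = c("chrom", "pos"), suffixes = c("_ref", "_other"))
  m[order(m$chrom, m$pos), , drop = FALSE]
}

#' Call differentially-methylated CpGs between two methylomes
#'
#' Per shared site passing the coverage filter in both samples, a two-sided
#' Fisher exact test on the 2x2 methylated/unmethylated table, BH adjustment
#' across all tested sites, and the DMC thresholds: absolute methylation
#' difference >= `diff_min` percentage points and q <= `q_max`. The sign
#' convention is reference minus comparator: hyper means higher methylation
#' in the reference cell.
#'
#' @param ref,other CpG record tables on the same site catalogue.
#' @param min_coverage read-depth filter (default 10).
#' @param diff_min DMC absolute methylation-difference threshold in
#'   percentage points (default 25).
#' @param q_max DMC q-value threshold (default 0.01).
#' @return data.frame of DMCs: chrom, pos, meth_diff (percentage points),
#'   p_value, q_value, direction; attribute "n_tested" carries the number of
#'   sites tested.
#' @export
call_dmcs <- function(ref, other, min_coverage = 10L, diff_min = 25,
                      q_max = 0.01) {
  m <- shared_sites(ref, other, min_coverage)
  if (nrow(m) == 0) {
    warning("no shared sites pass the coverage filter; returning empty DMC set")
    out <- data.frame(chrom = character(), pos = integer(),
                      meth_diff = numeric(), p_value = numeric(),
                      q_value = numeric(), direction = character())
    attr(out, "n_tested") <- 0L
    return(out)
  }
  diff <- 100 * (m$meth_count_ref / m$coverage_ref -
                   m$meth_count_other / m$coverage_other)
  p <- fisher_test_counts(m$meth_count_ref, m$coverage_ref,
                          m$meth_count_other, m$coverage_other)
  q <- benjamini_hochberg(p)
  keep <- abs(diff) >= diff_min & q <= q_max
  out <- data.frame(
    chrom = m$chrom[keep], pos = m$pos[keep], meth_diff = diff[keep],
    p_value = p[keep], q_value = q[keep],
    direction = ifelse(diff[keep] > 0, "hyper", "hypo"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_tested") <- nrow(m)
  out
}

#' Call differentially-methylated regions by tiling windows
#'
#' Fixed windows tile each chromosome; per window containing at least one
#' tested CpG, read counts are pooled per sample, the window methylation
#' difference is the difference of pooled proportions (percentage points,
#' reference minus comparator), and a Fisher test on the pooled 2x2 table is
#' BH-adjusted across windows. Qualifying windows (|mean_diff| >=
#' `diff_min`, q <= `q_candidate`) that are adjacent and share a direction
#' merge into one DMR; the merged mean_diff is recomputed from pooled counts
#' and the merged q is the minimum member-window q. Tiers: "candidate"
#' (|mean_diff| >= 20, q <= 0.01) and "significant" (additionally q <=
#' `q_significant` and >= `min_dmcs` qualifying DMCs inside).
#'
#' @param dmcs DMC table from [call_dmcs()] (used for the per-DMR DMC count).
#' @param ref,other CpG record tables.
#' @param min_coverage read-depth filter.
#' @param window,step tiling width and step in bp (> 0).
#' @param diff_min window mean-difference threshold in percentage points.
#' @param q_candidate,q_significant q-value tiers.
#' @param min_dmcs DMC count required for the significant tier.
#' @return data.frame of DMRs: chrom, start, end, mean_diff, p_value,
#'   q_value, n_dmcs, direction, tier.
#' @export
call_dmrs <- function(dmcs, ref, other, min_coverage = 10L, window = 1000L,
                      step = 1000L, diff_min = 20, q_candidate = 0.01,
                      q_significant = 0.001, min_dmcs = 5L) {
  if (window <= 0 || step <= 0) stop("window and step must be > 0")
  m <- shared_sites(ref, other, min_coverage)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      mean_diff = numeric(), p_value = numeric(),
                      q_value = numeric(), n_dmcs = integer(),
                      direction = character(), tier = character())
  if (nrow(m) == 0) return(empty)
  m$win <- (m$pos %/% step)
  key <- paste(m$chrom, m$win, sep = ":")
  keys <- sort(unique(key))
  ord <- match(keys, key)  # representative row per window for chrom/win
  sum_by <- function(v) {
    s <- tapply(v, key, sum)
    as.numeric(s[keys])
  }
  mr <- sum_by(m$meth_count_ref); cr <- sum_by(m$coverage_ref)
  mo <- sum_by(m$meth_count_other); co <- sum_by(m$coverage_other)
  wchrom <- m$chrom[ord]; wwin <- m$win[ord]
  diff <- 100 * (mr / cr - mo / co)
  p <- fisher_test_counts(mr, cr, mo, co)
  q <- benjamini_hochberg(p)
  qual <- abs(diff) >= diff_min & q <= q_candidate
  if (!any(qual)) return(empty)
  w <- data.frame(chrom = wchrom, win = wwin, mr = mr, cr = cr, mo = mo,
                  co = co, q = q, p = p,
                  direction = ifelse(diff > 0, "hyper", "hypo"),
                  stringsAsFactors = FALSE)[qual, , drop = FALSE]
  w <- w[order(w$chrom, w$win), , drop = FALSE]
  # merge runs of adjacent same-direction qualifying windows
  new_run <- c(TRUE, !(w$chrom[-1] == w$chrom[-nrow(w)] &
                         w$win[-1] == w$win[-nrow(w)] + 1 &
                         w$direction[-1] == w$direction[-nrow(w)]))
  run <- cumsum(new_run)
  out <- do.call(rbind, lapply(split(seq_len(nrow(w)), run), function(idx) {
    b <- w[idx, , drop = FALSE]
    mr <- sum(b$mr); cr <- sum(b$cr); mo <- sum(b$mo); co <- sum(b$co)
    data.frame(
      chrom = b$chrom[1],
      start = as.integer(min(b$win) * step),
      end = as.integer(max(b$win) * step + window),
      mean_diff = 100 * (mr / cr - mo / co),
      p_value = min(b$p), q_value = min(b$q),
      direction = b$direction[1],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out$n_dmcs <- vapply(seq_len(nrow(out)), function(i) {
    sum(dmcs$chrom == out$chrom[i] & dmcs$pos >= out$start[i] &
          dmcs$pos < out$end[i])
  }, integer(1))
  out$tier <- ifelse(out$q_value <= q_significant & out$n_dmcs >= min_dmcs,
                     "significant", "candidate")
  out[, c("chrom", "start", "end", "mean_diff", "p_value", "q_value",
          "n_dmcs", "direction", "tier")]
}

#' Cell-type-specific DMRs by set deduction
#'
#' A reference DMR survives iff it overlaps (by at least one base, any
#' direction) no DMR of any other cell type in the mapping — the set
#' subtraction of the reference DMR set against the union of all other cell
#' types' sets. Removed DMRs record the first blocking cell (in mapping
#' order).
#'
#' @param dmr_sets named list, cell type -> DMR data.frame (chrom, start,
#'   end, ...).
#' @param reference name of the reference cell (must be in the mapping).
#' @param tier if non-NULL, subset every set to this tier first
#'   ("significant" by default use NULL to keep all rows).
#' @return list of class "cell_specific_dmrs": reference_cell, dmrs
#'   (survivors), removed (with a blocking_cell column).
#' @export
cell_specific_subtraction <- function(dmr_sets, reference, tier = NULL) {
  if (!reference %in% names(dmr_sets)) {
    stop(sprintf("reference cell '%s' missing from the DMR mapping", reference))
  }
  pick <- function(d) {
    if (!is.null(tier) && "tier" %in% names(d)) d[d$tier == tier, , drop = FALSE]
    else d
  }
  ref <- pick(dmr_sets[[reference]])
  others <- setdiff(names(dmr_sets), reference)
  blocking <- rep(NA_character_, nrow(ref))
  if (nrow(ref) > 0) {
    ref_gr <- as_granges(ref)
    for (cell in others) {
      d <- pick(dmr_sets[[cell]])
      if (nrow(d) == 0) next
      hit <- IRanges::overlapsAny(ref_gr, as_granges(d), ignore.strand = TRUE)
      blocking[is.na(blocking) & hit] <- cell
    }
  }
  surv <- is.na(blocking)
  removed <- ref[!surv, , drop = FALSE]
  if (nrow(removed) > 0) removed$blocking_cell <- blocking[!surv]
  else removed$blocking_cell <- character(0)
  structure(list(reference_cell = reference,
                 dmrs = ref[surv, , drop = FALSE],
                 removed = removed),
            class = "cell_specific_dmrs")
}

#' Write DMCs or DMRs as BED6+ with statistics columns
#' @param dmrs DMR data.frame from [call_dmrs()].
#' @param path output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.\t%s\t%s\t%d\t%s",
                   dmrs$chrom, dmrs$start, dmrs$end,
                   paste0("DMR", seq_len(nrow(dmrs))),
                   format(dmrs$mean_diff, trim = TRUE, digits = 6),
                   format(dmrs$q_value, trim = TRUE, digits = 6),
                   dmrs$direction, dmrs$n_dmcs, dmrs$tier)
  writeLines(lines, path)
  invisible(path)
}
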