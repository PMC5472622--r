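#' @keywords internal
"_PACKAGE"

#' @importFrom stats density dnorm rnorm rgamma rbinom rnbinom rbeta runif
#'   median quantile var sd cor p.adjust dhyper ks.test pbeta dgamma setNames
#'   qbeta
#' @importFrom utils read.delim write.table
NULL

# ---- interval helpers -------------------------------------------------------
# Internal coordinates are 0-based half-open [start, end); GRanges is 1-based
# closed, so start+1 on the way in and start-1 on the way out.

#' Construct a 0-based half-open genomic interval table
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param name optional interval names.
#' @param strand optional strand ("+", "-" or ".").
#' @return A data.frame with columns chrom, start, end, name, strand.
#' @export
genomic_intervals <- function(chrom, start, end, name = ".", strand = ".") {
  stopifnot(length(start) == length(end))
  chrom <- rep_len(as.character(chrom), length(start))
  if (length(start) > 0 && any(start >= end)) {
    stop("malformed interval: start must be < end (0-based half-open)")
  }
  if (length(chrom) > 0 && any(!nzchar(chrom))) stop("empty chromosome name")
  data.frame(
    chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    name = rep_len(as.character(name), length(chrom)),
    strand = rep_len(as.character(strand), length(chrom)),
    stringsAsFactors = FALSE
  )
}

# intervals data.frame -> GRanges
as_granges <- function(x) {
  if (is.null(x) || nrow(x) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x)) {
      ifelse(x$strand %in% c("+", "-"), x$strand, "*")
    } else "*"
  )
}

# GRanges -> intervals data.frame (strand dropped unless keep_strand)
as_intervals <- function(gr, name = ".") {
  if (length(gr) == 0) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  genomic_intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = name
  )
}

# set operations on interval tables, strand-blind, result reduced/sorted
iv_reduce <- function(x) as_intervals(GenomicRanges::reduce(as_granges(x), ignore.strand = TRUE))
iv_union <- function(x, y) {
  as_intervals(GenomicRanges::union(as_granges(x), as_granges(y), ignore.strand = TRUE))
}
iv_intersect <- function(x, y) {
  as_intervals(GenomicRanges::intersect(as_granges(x), as_granges(y), ignore.strand = TRUE))
}
iv_setdiff <- function(x, y) {
  as_intervals(GenomicRanges::setdiff(as_granges(x), as_granges(y), ignore.strand = TRUE))
}

# total bases covered by an interval table (after reduce)
iv_bases <- function(x) {
  r <- iv_reduce(x)
  if (nrow(r) == 0) return(0L)
  sum(r$end - r$start)
}

# which rows of `sites` (chrom, pos) fall inside any interval of `iv`
sites_in_intervals <- function(sites, iv) {
  if (nrow(sites) == 0 || is.null(iv) || nrow(iv) == 0) {
    return(rep(FALSE, nrow(sites)))
  }
  site_gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L)
  )
  IRanges::overlapsAny(site_gr, as_granges(iv), ignore.strand = TRUE)
}

# ---- RNG streams ------------------------------------------------------------
# One stream per generator: derive a child seed from (master_seed, stream_name)
# so the generators stay decoupled. Cheap string hash folded into [0, 2^31).
derive_seed <- function(master_seed, stream_name) {
  h <- 0
  for (cp in utf8ToInt(stream_name)) h <- (h * 31 + cp) %% 2147483647
  as.integer((as.numeric(master_seed) %% 2147483647 * 7919 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
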