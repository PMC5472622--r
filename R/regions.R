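# The six-region CGI/shore/promoter partition (Regions I-VI), feature
# assignment of CpG sites, per-region methylation profiles and DMR overlap
# with tumor-suppressor gene segments.

#' Promoter windows (TSS +/- halfwidth) for a gene catalogue
#'
#' @param genes refFlat-style gene-model data.frame.
#' @param halfwidth promoter half-width in bp (2,000 bp window by default).
#' @param chrom_sizes optional named vector for clipping at chromosome ends.
#' @return interval data.frame, one window per gene (name = gene_id).
#' @export
promoter_windows <- function(genes, halfwidth = 1000L, chrom_sizes = NULL) {
  tss <- ifelse(genes$strand == "-", genes$tx_end, genes$tx_start)
  lo <- pmax(0L, tss - halfwidth)
  hi <- tss + halfwidth
  if (!is.null(chrom_sizes)) {
    hi <- pmin(hi, unname(chrom_sizes[genes$chrom]))
  }
  genomic_intervals(genes$chrom, lo, hi, name = genes$gene_id,
                    strand = genes$strand)
}

#' Build the six-region CGI/shore/promoter partition
#'
#' CpG islands are merged, shores are the `shore_flank` bp bands on each side
#' of an island with island bases removed, and promoters are the merged
#' TSS +/- `promoter_halfwidth` windows. The six regions:
#' \itemize{
#'   \item I  (CGI.NP)   islands outside promoters
#'   \item II (CGIS.NP)  shores outside promoters
#'   \item III (P.CGI)   islands within promoters
#'   \item IV (P.CGIS)   shores within promoters
#'   \item V  (P.NCGI)   promoter bases outside islands
#'   \item VI (P.NCGIS)  promoter bases outside islands and shores
#' }
#'
#' @param cgis CpG-island interval data.frame.
#' @param genes gene-model data.frame (for TSSs); alternatively pass
#'   precomputed promoter intervals via `promoters`.
#' @param shore_flank shore width on each side of an island, bp.
#' @param promoter_halfwidth promoter half-width, bp.
#' @param promoters optional promoter intervals overriding `genes`.
#' @param chrom_sizes optional named vector for clipping.
#' @return list of class "region_partition" with interval data.frames
#'   CGI.NP, CGIS.NP, P.CGI, P.CGIS, P.NCGI, P.NCGIS plus the underlying
#'   cgi, shore, promoter tracks.
#' @export
build_partition <- function(cgis, genes = NULL, shore_flank = 1000L,
                            promoter_halfwidth = 1000L, promoters = NULL,
                            chrom_sizes = NULL) {
  cgi <- iv_reduce(cgis)
  if (is.null(promoters)) {
    if (is.null(genes)) stop("supply either genes or promoters")
    promoters <- promoter_windows(genes, promoter_halfwidth, chrom_sizes)
  }
  prom <- iv_reduce(promoters)
  shore_raw <- if (nrow(cgi) > 0) {
    rbind(
      genomic_intervals(cgi$chrom, pmax(0L, cgi$start - shore_flank), cgi$start),
      genomic_intervals(cgi$chrom, cgi$end, cgi$end + shore_flank)
    )
  } else {
    genomic_intervals(character(), integer(), integer())
  }
  shore <- iv_setdiff(shore_raw, cgi)
  structure(list(
    CGI.NP = iv_setdiff(cgi, prom),
    CGIS.NP = iv_setdiff(shore, prom),
    P.CGI = iv_intersect(cgi, prom),
    P.CGIS = iv_intersect(shore, prom),
    P.NCGI = iv_setdiff(prom, cgi),
    P.NCGIS = iv_setdiff(prom, iv_union(cgi, shore)),
    cgi = cgi, shore = shore, promoter = prom
  ), class = "region_partition")
}

#' Assign CpG sites (or DMCs) to genomic features
#'
#' Two independent single-valued labels per site: a gene-context label with
#' precedence promoter > exon > intron > intergenic, and a CpG-context label
#' with precedence CGI > shore > open sea.
#'
#' @param sites data.frame with chrom, pos (0-based).
#' @param genes gene-model data.frame (exons/introns derived per gene).
#' @param cgis CpG-island intervals.
#' @param shore_flank,promoter_halfwidth,chrom_sizes as in
#'   [build_partition()].
#' @return list with `assignments` (per-site gene_context, cpg_context) and
#'   `fractions` (named proportion vectors per hierarchy).
#' @export
assign_features <- function(sites, genes, cgis, shore_flank = 1000L,
                            promoter_halfwidth = 1000L, chrom_sizes = NULL) {
  prom <- promoter_windows(genes, promoter_halfwidth, chrom_sizes)
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    genomic_intervals(genes$chrom[i], genes$exon_starts[[i]],
                      genes$exon_ends[[i]])
  }))
  introns <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    s <- genes$exon_starts[[i]]; e <- genes$exon_ends[[i]]
    if (length(s) < 2) return(NULL)
    genomic_intervals(genes$chrom[i], e[-length(e)], s[-1])
  }))
  cgi <- iv_reduce(cgis)
  shore <- iv_setdiff(
    if (nrow(cgi) > 0) rbind(
      genomic_intervals(cgi$chrom, pmax(0L, cgi$start - shore_flank), cgi$start),
      genomic_intervals(cgi$chrom, cgi$end, cgi$end + shore_flank)
    ) else genomic_intervals(character(), integer(), integer()),
    cgi
  )
  gene_context <- rep("intergenic", nrow(sites))
  gene_context[sites_in_intervals(sites, introns)] <- "intron"
  gene_context[sites_in_intervals(sites, exons)] <- "exon"
  gene_context[sites_in_intervals(sites, prom)] <- "promoter"
  cpg_context <- rep("open sea", nrow(sites))
  cpg_context[sites_in_intervals(sites, shore)] <- "shore"
  cpg_context[sites_in_intervals(sites, cgi)] <- "CGI"
  assignments <- data.frame(chrom = sites$chrom, pos = sites$pos,
                            gene_context = gene_context,
                            cpg_context = cpg_context,
                            stringsAsFactors = FALSE)
  frac <- function(x, levels) {
    t <- table(factor(x, levels = levels))
    stats::setNames(as.numeric(t) / max(1L, length(x)), levels)
  }
  list(
    assignments = assignments,
    fractions = list(
      gene_context = frac(gene_context,
                          c("promoter", "exon", "intron", "intergenic")),
      cpg_context = frac(cpg_context, c("CGI", "shore", "open sea"))
    )
  )
}

#' Per-region methylation histograms and quartiles
#'
#' For each of the six partition regions, a 20-bin histogram of methylation
#' percent over the CpGs falling inside the region. If TF peaks are
#' supplied, only regions overlapping at least one peak are profiled (the
#' TF-binding restriction).
#'
#' @param methylome CpG record table.
#' @param partition a [build_partition()] result.
#' @param tf_peaks optional interval data.frame of peaks.
#' @param min_coverage coverage filter.
#' @return list per region: counts (20 bins over [0, 100]), breaks,
#'   quartiles, n; regions with zero covered CpGs are flagged
#'   (`empty = TRUE`).
#' @export
region_methylation_profiles <- function(methylome, partition, tf_peaks = NULL,
                                        min_coverage = 10L) {
  m <- methylome[methylome$coverage >= min_coverage, , drop = FALSE]
  breaks <- seq(0, 100, by = 5)
  region_names <- c("CGI.NP", "CGIS.NP", "P.CGI", "P.CGIS", "P.NCGI", "P.NCGIS")
  out <- lapply(region_names, function(rn) {
    iv <- partition[[rn]]
    if (!is.null(tf_peaks) && nrow(iv) > 0) {
      hit <- IRanges::overlapsAny(as_granges(iv), as_granges(tf_peaks),
                                  ignore.strand = TRUE)
      iv <- iv[hit, , drop = FALSE]
    }
    inside <- sites_in_intervals(m, iv)
    pct <- 100 * m$meth_count[inside] / m$coverage[inside]
    if (length(pct) == 0) {
      return(list(empty = TRUE, n = 0L,
                  counts = rep(0L, length(breaks) - 1), breaks = breaks,
                  quartiles = rep(NA_real_, 3)))
    }
    h <- graphics::hist(pct, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = FALSE)
    list(empty = FALSE, n = length(pct), counts = h$counts, breaks = breaks,
         quartiles = unname(quantile(pct, c(0.25, 0.5, 0.75))))
  })
  stats::setNames(out, region_names)
}

#' Overlap DMRs with tumor-suppressor gene segments
#'
#' One record per (DMR, TSG, segment) pair sharing at least one base, over
#' the segments promoter, 5'UTR, 3'UTR, CDS and intron; per-direction gene
#' counts are deduplicated (a gene hit by several DMRs or in several
#' segments counts once per direction).
#'
#' @param dmrs DMR data.frame (chrom, start, end, direction).
#' @param tsg_ids character vector of TSG gene ids; ids absent from the gene
#'   catalogue are skipped with a message.
#' @param genes gene-model data.frame.
#' @param promoter_halfwidth promoter half-width for the promoter segment.
#' @return list with `overlaps` (data.frame dmr_id, gene_id, segment,
#'   direction) and `gene_counts` (named vector: hyper, hypo).
#' @export
overlap_tsg <- function(dmrs, tsg_ids, genes, promoter_halfwidth = 1000L) {
  known <- tsg_ids %in% genes$gene_id
  if (any(!known)) {
    message(sprintf("%d TSG id(s) not in the gene catalogue; skipped",
                    sum(!known)))
  }
  tsg <- genes[genes$gene_id %in% tsg_ids[known], , drop = FALSE]
  seg_names <- c(promoter = "promoter", utr5 = "5'UTR", utr3 = "3'UTR",
                 cds = "CDS", intron = "intron")
  recs <- list()
  if (nrow(dmrs) > 0 && nrow(tsg) > 0) {
    dmr_gr <- as_granges(dmrs)
    for (i in seq_len(nrow(tsg))) {
      segs <- derive_segments(tsg[i, ], promoter_halfwidth)
      for (sk in names(seg_names)) {
        iv <- segs[[sk]]
        if (nrow(iv) == 0) next
        hit <- which(IRanges::overlapsAny(dmr_gr, as_granges(iv),
                                          ignore.strand = TRUE))
        for (d in hit) {
          recs[[length(recs) + 1]] <- data.frame(
            dmr_id = d, gene_id = tsg$gene_id[i], segment = seg_names[[sk]],
            direction = dmrs$direction[d], stringsAsFactors = FALSE)
        }
      }
    }
  }
  overlaps <- if (length(recs) > 0) do.call(rbind, recs) else
    data.frame(dmr_id = integer(), gene_id = character(),
               segment = character(), direction = character())
  rownames(overlaps) <- NULL
  counts <- c(
    hyper = length(unique(overlaps$gene_id[overlaps$direction == "hyper"])),
    hypo = length(unique(overlaps$gene_id[overlaps$direction == "hypo"]))
  )
  list(overlaps = overlaps, gene_counts = counts)
}
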