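# Readers and writers for the standard formats the pipeline touches.
# Internally everything is 0-based half-open; 1-based coordinates appear only
# at the methylKit-TSV boundary. Readers sort by (chrom, pos) and skip
# '#'-prefixed comment lines.

#' Construct a per-CpG methylation record table
#'
#' The internal methylome representation: one row per CpG with strand-aware
#' 0-based position, read coverage and methylated-read count.
#'
#' @param chrom chromosome names.
#' @param pos 0-based positions.
#' @param strand "+", "-" or "." (unknown).
#' @param coverage total read count at the site.
#' @param meth_count methylated read count, 0 <= meth_count <= coverage.
#' @return data.frame with columns chrom, pos, strand, coverage, meth_count.
#' @export
cpg_records <- function(chrom, pos, strand = ".", coverage, meth_count) {
  coverage <- as.integer(coverage)
  meth_count <- as.integer(meth_count)
  if (any(coverage < 0)) stop("negative coverage")
  if (any(meth_count < 0) || any(meth_count > coverage)) {
    stop("meth_count must satisfy 0 <= meth_count <= coverage")
  }
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    strand = rep_len(as.character(strand), length(chrom)),
    coverage = coverage, meth_count = meth_count,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

read_tsv_skip_comments <- function(path, colClasses = NA) {
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE,
             colClasses = colClasses)
}

#' Read a methylKit-style per-CpG TSV
#'
#' Expects the methylKit column layout: chrBase, chr, base (1-based), strand
#' (F/R), coverage, freqC, freqT with freqC + freqT = 100. The methylated
#' count is reconstructed as round(coverage * freqC / 100), rounding half
#' away from zero (freqC is a percentage with limited precision).
#'
#' @param path file path.
#' @return CpG record table (see [cpg_records()]); positions converted to
#'   0-based, strand F/R mapped to +/-.
#' @export
read_methylkit_tsv <- function(path) {
  # strand must stay character: a column of bare F would parse as logical
  df <- read_tsv_skip_comments(path, colClasses = c(strand = "character"))
  need <- c("chrBase", "chr", "base", "strand", "coverage", "freqC", "freqT")
  if (!all(need %in% names(df))) {
    stop("methylKit TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) {
    return(cpg_records(character(), integer(), character(), integer(), integer()))
  }
  bad <- which(abs(df$freqC + df$freqT - 100) > 0.5)
  if (length(bad) > 0) {
    stop(sprintf("malformed methylKit row at data line %d: freqC + freqT = %g",
                 bad[1], df$freqC[bad[1]] + df$freqT[bad[1]]))
  }
  if (any(df$coverage < 0)) {
    stop(sprintf("malformed methylKit row at data line %d: negative coverage",
                 which(df$coverage < 0)[1]))
  }
  strand <- c(F = "+", R = "-")[df$strand]
  strand[is.na(strand)] <- "."
  cpg_records(
    chrom = df$chr, pos = df$base - 1L, strand = strand,
    coverage = df$coverage,
    meth_count = round_half_away(df$coverage * df$freqC / 100)
  )
}

#' Write a methylKit-style per-CpG TSV
#'
#' @param records CpG record table.
#' @param path output path.
#' @export
write_methylkit_tsv <- function(records, path) {
  freqC <- ifelse(records$coverage > 0,
                  100 * records$meth_count / records$coverage, 0)
  out <- data.frame(
    chrBase = paste0(records$chrom, ".", records$pos + 1L),
    chr = records$chrom,
    base = records$pos + 1L,
    strand = c(`+` = "F", `-` = "R", `.` = "F")[records$strand],
    coverage = records$coverage,
    freqC = round(freqC, 2),
    freqT = round(100 - freqC, 2),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Bismark-style coverage bedGraph
#'
#' Columns: chrom, start (0-based), end, percent methylation, count
#' methylated, count unmethylated. The percent column is cross-checked
#' against the counts (tolerance 0.5 percentage points).
#'
#' @param path file path.
#' @return CpG record table with strand ".".
#' @export
read_bedgraph_coverage <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(cpg_records(character(), integer(), character(), integer(), integer()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 6)) {
    stop(sprintf("malformed bedGraph row at line %d: expected 6 fields",
                 which(lengths(f) != 6)[1]))
  }
  m <- do.call(rbind, f)
  pct <- as.numeric(m[, 4])
  cm <- as.integer(m[, 5])
  cu <- as.integer(m[, 6])
  cov <- cm + cu
  implied <- ifelse(cov > 0, 100 * cm / cov, 0)
  bad <- which(abs(pct - implied) > 0.5)
  if (length(bad) > 0) {
    stop(sprintf(
      "malformed bedGraph row at line %d: percent %g inconsistent with counts (%g)",
      bad[1], pct[bad[1]], implied[bad[1]]))
  }
  cpg_records(chrom = m[, 1], pos = as.integer(m[, 2]), strand = ".",
              coverage = cov, meth_count = cm)
}

#' Write a Bismark-style coverage bedGraph
#' @param records CpG record table.
#' @param path output path.
#' @export
write_bedgraph_coverage <- function(records, path) {
  pct <- ifelse(records$coverage > 0,
                100 * records$meth_count / records$coverage, 0)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   records$chrom, records$pos, records$pos + 1L,
                   format(pct, trim = TRUE, digits = 15),
                   records$meth_count, records$coverage - records$meth_count)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write BED6 interval files
#'
#' BED is 0-based half-open, matching the internal convention. Missing
#' name/score/strand columns default to ".", 0, ".".
#'
#' @param path file path.
#' @return interval data.frame with columns chrom, start, end, name, score,
#'   strand.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(lines)]
  if (length(lines) == 0) {
    out <- genomic_intervals(character(), integer(), integer())
    out$score <- numeric(0)
    return(out[, c("chrom", "start", "end", "name", "score", "strand")])
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  n <- min(lengths(f))
  m <- do.call(rbind, lapply(f, function(x) x[seq_len(min(6, n))]))
  out <- genomic_intervals(
    chrom = m[, 1], start = as.integer(m[, 2]), end = as.integer(m[, 3]),
    name = if (n >= 4) m[, 4] else ".",
    strand = if (n >= 6) m[, 6] else "."
  )
  out$score <- if (n >= 5) suppressWarnings(as.numeric(m[, 5])) else 0
  out[order(out$chrom, out$start), c("chrom", "start", "end", "name", "score", "strand")]
}

#' @rdname read_bed
#' @param intervals interval data.frame (chrom, start, end; optional name,
#'   score, strand).
#' @export
write_bed <- function(intervals, path) {
  name <- if ("name" %in% names(intervals)) intervals$name else "."
  score <- if ("score" %in% names(intervals)) intervals$score else 0
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   intervals$chrom, intervals$start, intervals$end,
                   name, format(score, trim = TRUE), strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a refFlat gene-model table
#'
#' Standard refFlat column order: geneName, name, chrom, strand, txStart,
#' txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds (exon lists
#' comma-separated, 0-based half-open).
#'
#' @param path file path.
#' @return data.frame with one row per transcript; exon_starts/exon_ends are
#'   list columns of integer vectors.
#' @export
read_refflat <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(gene_id = character(), tx_id = character(),
                      chrom = character(), strand = character(),
                      tx_start = integer(), tx_end = integer(),
                      cds_start = integer(), cds_end = integer()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  m <- do.call(rbind, f)
  parse_list <- function(s) {
    lapply(strsplit(s, ",", fixed = TRUE), function(x) as.integer(x[nzchar(x)]))
  }
  g <- data.frame(
    gene_id = m[, 1], tx_id = m[, 2], chrom = m[, 3], strand = m[, 4],
    tx_start = as.integer(m[, 5]), tx_end = as.integer(m[, 6]),
    cds_start = as.integer(m[, 7]), cds_end = as.integer(m[, 8]),
    stringsAsFactors = FALSE
  )
  g$exon_starts <- parse_list(m[, 10])
  g$exon_ends <- parse_list(m[, 11])
  bad <- which(lengths(g$exon_starts) != lengths(g$exon_ends))
  if (length(bad) > 0) {
    stop(sprintf("gene %s: exonStarts and exonEnds have unequal lengths",
                 g$gene_id[bad[1]]))
  }
  g[order(g$chrom, g$tx_start), , drop = FALSE]
}

#' Write a refFlat gene-model table
#' @param genes gene-model data.frame as from [read_refflat()].
#' @param path output path.
#' @export
write_refflat <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    paste(genes$gene_id[i], genes$tx_id[i], genes$chrom[i], genes$strand[i],
          genes$tx_start[i], genes$tx_end[i], genes$cds_start[i],
          genes$cds_end[i], length(genes$exon_starts[[i]]),
          paste0(paste(genes$exon_starts[[i]], collapse = ","), ","),
          paste0(paste(genes$exon_ends[[i]], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Derive genomic segments (promoter, UTRs, CDS, introns) from a gene model
#'
#' The 5' UTR is the exonic sequence between the transcription start side
#' and the CDS start on the transcribed strand; the 3' UTR is symmetric;
#' introns are the gaps between exons; the promoter is the 2,000 bp window
#' centered on the TSS (TSS +/- `promoter_halfwidth`), clipped at chromosome
#' bounds. A non-coding gene (cds_start == cds_end) yields no UTR/CDS
#' segments, only gene body, introns and promoter.
#'
#' @param gene one row of a gene-model data.frame.
#' @param promoter_halfwidth half-width of the promoter window in bp.
#' @param chrom_size optional chromosome length for clipping.
#' @return named list of interval data.frames: promoter, utr5, utr3, cds,
#'   intron, gene_body (possibly zero-row).
#' @export
derive_segments <- function(gene, promoter_halfwidth = 1000L, chrom_size = NULL) {
  ex_s <- gene$exon_starts[[1]]
  ex_e <- gene$exon_ends[[1]]
  stopifnot(length(ex_s) == length(ex_e))
  o <- order(ex_s)
  ex_s <- ex_s[o]; ex_e <- ex_e[o]
  if (any(ex_s >= ex_e)) stop("malformed exon interval")
  if (length(ex_s) > 1 && any(ex_s[-1] < ex_e[-length(ex_e)])) {
    stop("overlapping exons")
  }
  chrom <- gene$chrom
  strand <- gene$strand
  iv <- function(s, e) {
    keep <- s < e
    genomic_intervals(rep(chrom, sum(keep)), s[keep], e[keep], strand = strand)
  }
  empty <- genomic_intervals(character(), integer(), integer())
  exons <- iv(ex_s, ex_e)
  introns <- if (length(ex_s) > 1) iv(ex_e[-length(ex_e)], ex_s[-1]) else empty
  coding <- gene$cds_start < gene$cds_end
  if (coding) {
    cds <- iv(pmax(ex_s, gene$cds_start), pmin(ex_e, gene$cds_end))
    left_utr <- iv(pmin(ex_s, gene$cds_start), pmin(ex_e, gene$cds_start))
    right_utr <- iv(pmax(ex_s, gene$cds_end), pmax(ex_e, gene$cds_end))
    if (strand == "-") { utr5 <- right_utr; utr3 <- left_utr }
    else { utr5 <- left_utr; utr3 <- right_utr }
  } else {
    cds <- empty; utr5 <- empty; utr3 <- empty
  }
  tss <- if (strand == "-") gene$tx_end else gene$tx_start
  p_lo <- max(0L, tss - promoter_halfwidth)
  p_hi <- tss + promoter_halfwidth
  if (!is.null(chrom_size)) p_hi <- min(p_hi, chrom_size)
  promoter <- genomic_intervals(chrom, p_lo, p_hi, strand = strand)
  list(
    promoter = promoter, utr5 = utr5, utr3 = utr3, cds = cds,
    intron = introns,
    gene_body = genomic_intervals(chrom, gene$tx_start, gene$tx_end,
                                  strand = strand)
  )
}

#' Read a DESeq-style differential-expression table
#'
#' Expects tab-separated columns id, log2FoldChange, pval, padj (extra
#' columns kept).
#'
#' @param path file path.
#' @return data.frame with at least those four columns.
#' @export
read_dge_table <- function(path) {
  df <- read_tsv_skip_comments(path)
  need <- c("id", "log2FoldChange", "pval", "padj")
  if (!all(need %in% names(df))) {
    stop("DGE table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_dge_table
#' @param dge data.frame with columns id, log2FoldChange, pval, padj.
#' @export
write_dge_table <- function(dge, path) {
  write.table(dge, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain gene-symbol list (one id per line), e.g. a TSG catalogue
#' @param path file path.
#' @return character vector of ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x[!startsWith(x, "#")])
  x[nzchar(x)]
}
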