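# Synthetic multi-cell-type data: a miniature genome, RRBS-style methylomes
# with planted cell-type-specific DMRs, expression tables generated from the
# methylation-expression regression model with known coefficients, and TF
# peak sets whose promoter methylation is drawn from the background or from a
# shifted beta. Every generator records full ground truth and is
# deterministic under its seed; seeds for the internal streams are derived
# from (master seed, stream name) so the generators stay decoupled.

#' Specify a miniature multi-chromosome genome
#'
#' @param chrom_sizes named integer vector, chromosome name -> length (bp).
#' @param n_genes number of genes to place.
#' @param n_cgis number of CpG islands to place.
#' @param n_cpgs number of CpG sites in the shared RRBS site catalogue.
#' @param seed integer RNG seed.
#' @return object of class "genome_spec".
#' @export
genome_spec <- function(chrom_sizes, n_genes = 20L, n_cgis = 10L,
                        n_cpgs = 2000L, seed = 1L) {
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be > 0")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("chrom_sizes must be a named vector")
  }
  structure(list(chrom_sizes = chrom_sizes, n_genes = as.integer(n_genes),
                 n_cgis = as.integer(n_cgis), n_cpgs = as.integer(n_cpgs),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Specify a cell type's methylation landscape
#'
#' Methylation proportions are drawn from a beta mixture whose number of
#' components encodes the unimodal/bimodal/trimodal landscape observed in
#' real methylomes; coverage is negative-binomial, floored at
#' `min_coverage_floor` so sites both passing and failing the read-depth
#' filter are produced.
#'
#' @param modality "unimodal", "bimodal" or "trimodal".
#' @param mixture_weights component proportions, summing to 1.
#' @param component_params list of c(alpha, beta) shape pairs, one per
#'   component.
#' @param coverage_mean,coverage_dispersion negative-binomial mean and size.
#' @param min_coverage_floor minimum coverage (default 1).
#' @return object of class "methylome_spec".
#' @export
methylome_spec <- function(modality = c("bimodal", "unimodal", "trimodal"),
                           mixture_weights = NULL, component_params = NULL,
                           coverage_mean = 30, coverage_dispersion = 5,
                           min_coverage_floor = 1L) {
  modality <- match.arg(modality)
  k <- c(unimodal = 1L, bimodal = 2L, trimodal = 3L)[[modality]]
  if (is.null(component_params)) {
    component_params <- list(c(2, 8), c(8, 2), c(5, 5))[seq_len(k)]
  }
  if (is.null(mixture_weights)) mixture_weights <- rep(1 / k, k)
  if (length(mixture_weights) != k || length(component_params) != k) {
    stop("number of mixture components must match the modality")
  }
  if (any(mixture_weights < 0) || abs(sum(mixture_weights) - 1) > 1e-9) {
    stop("mixture_weights must be non-negative and sum to 1")
  }
  shp <- unlist(component_params)
  if (any(shp <= 0)) stop("beta shape parameters must be > 0")
  structure(list(modality = modality, mixture_weights = mixture_weights,
                 component_params = component_params,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 min_coverage_floor = as.integer(min_coverage_floor)),
            class = "methylome_spec")
}

#' Describe a planted cell-type-specific DMR
#'
#' @param chrom,start,end interval (0-based half-open).
#' @param target_cell cell type carrying the shift.
#' @param direction "hyper" (shift up in the target cell) or "hypo".
#' @param effect_size methylation-proportion shift in (0, 1].
#' @param n_cpgs CpG sites guaranteed inside the interval (>= 5 so the
#'   significant-DMR rule can recover it).
#' @return object of class "planted_dmr".
#' @export
planted_dmr <- function(chrom, start, end, target_cell,
                        direction = c("hyper", "hypo"),
                        effect_size = 0.4, n_cpgs = 8L) {
  direction <- match.arg(direction)
  if (effect_size <= 0 || effect_size > 1) stop("effect_size must be in (0, 1]")
  if (n_cpgs < 5) stop("n_cpgs must be >= 5 for the planted DMR to be recoverable")
  if (start >= end) stop("malformed interval")
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), target_cell = target_cell,
                 direction = direction, effect_size = effect_size,
                 n_cpgs = as.integer(n_cpgs)),
            class = "planted_dmr")
}

#' Generate gene models and CpG islands for a synthetic genome
#'
#' Genes are non-overlapping two-exon transcripts on random strands; CpG
#' islands are 300-1,500 bp intervals, a portion of them near a TSS so the
#' promoter/island partition has all six region classes populated.
#'
#' @param genome a [genome_spec()].
#' @return list with elements `genes` (refFlat-style data.frame) and `cgis`
#'   (interval data.frame).
#' @export
simulate_gene_models <- function(genome) {
  stopifnot(inherits(genome, "genome_spec"))
  with_seed(derive_seed(genome$seed, "gene_models"), {
    chroms <- names(genome$chrom_sizes)
    # apportion genes to chromosomes by length
    w <- genome$chrom_sizes / sum(genome$chrom_sizes)
    per <- pmax(1L, round_half_away(genome$n_genes * w))
    rows <- list()
    for (ci in seq_along(chroms)) {
      L <- genome$chrom_sizes[[ci]]
      n <- per[ci]
      slot <- floor(L / n)
      for (k in seq_len(n)) {
        lo <- (k - 1) * slot + 2000
        span <- min(slot - 4000, round(runif(1, 3000, 12000)))
        if (span < 2000) next
        tx_s <- as.integer(lo + floor(runif(1, 0, max(1, slot - span - 4000))))
        tx_e <- as.integer(tx_s + span)
        strand <- sample(c("+", "-"), 1)
        # two exons with an intron gap
        e1 <- as.integer(tx_s + max(200, floor(span * 0.25)))
        i_end <- as.integer(e1 + max(200, floor(span * 0.25)))
        cds_s <- as.integer(tx_s + floor(0.1 * span))
        cds_e <- as.integer(tx_e - floor(0.1 * span))
        rows[[length(rows) + 1]] <- list(
          gene_id = sprintf("gene%03d", length(rows) + 1),
          tx_id = sprintf("tx%03d", length(rows) + 1),
          chrom = chroms[ci], strand = strand,
          tx_start = tx_s, tx_end = tx_e,
          cds_start = cds_s, cds_end = cds_e,
          exon_starts = list(c(tx_s, i_end)),
          exon_ends = list(c(e1, tx_e))
        )
      }
    }
    genes <- do.call(rbind, lapply(rows, function(r) {
      d <- data.frame(r[c("gene_id", "tx_id", "chrom", "strand", "tx_start",
                          "tx_end", "cds_start", "cds_end")],
                      stringsAsFactors = FALSE)
      d$exon_starts <- r$exon_starts
      d$exon_ends <- r$exon_ends
      d
    }))
    # CGIs: half near a TSS, half intergenic
    n_cgi <- genome$n_cgis
    cgi_rows <- list()
    for (k in seq_len(n_cgi)) {
      width <- as.integer(round(runif(1, 300, 1500)))
      if (k %% 2 == 0 && nrow(genes) > 0) {
        g <- genes[sample(nrow(genes), 1), ]
        tss <- if (g$strand == "-") g$tx_end else g$tx_start
        s <- max(0L, as.integer(tss - floor(width / 2) +
                                  round(runif(1, -400, 400))))
        chrom <- g$chrom
      } else {
        chrom <- sample(names(genome$chrom_sizes), 1)
        s <- as.integer(floor(runif(1, 0, genome$chrom_sizes[[chrom]] - width)))
      }
      e <- min(s + width, genome$chrom_sizes[[chrom]])
      cgi_rows[[k]] <- list(chrom = chrom, start = s, end = as.integer(e))
    }
    cgis <- do.call(rbind, lapply(cgi_rows, as.data.frame))
    cgis <- iv_reduce(genomic_intervals(cgis$chrom, cgis$start, cgis$end))
    cgis$name <- sprintf("CGI%03d", seq_len(nrow(cgis)))
    list(genes = genes, cgis = cgis)
  })
}

draw_mixture_proportions <- function(n, spec) {
  comp <- sample.int(length(spec$mixture_weights), n, replace = TRUE,
                     prob = spec$mixture_weights)
  a <- vapply(spec$component_params, `[`, numeric(1), 1L)
  b <- vapply(spec$component_params, `[`, numeric(1), 2L)
  rbeta(n, a[comp], b[comp])
}

# numerical quantile function of a beta mixture, vectorized over u
mixture_quantile <- function(u, spec) {
  a <- vapply(spec$component_params, `[`, numeric(1), 1L)
  b <- vapply(spec$component_params, `[`, numeric(1), 2L)
  w <- spec$mixture_weights
  grid <- seq(0, 1, length.out = 2001)
  cdf <- rowSums(vapply(seq_along(w), function(k) {
    w[k] * pbeta(grid, a[k], b[k])
  }, numeric(length(grid))))
  # make strictly increasing for interpolation
  cdf <- cummax(cdf + seq_along(cdf) * 1e-12)
  stats::approx(cdf, grid, xout = clamp(u, min(cdf), max(cdf)),
                rule = 2)$y
}

#' Simulate multi-cell-type RRBS methylomes with planted DMRs
#'
#' CpG positions are drawn once and shared across cell types (RRBS enriches
#' a common set of MspI fragments); per-cell missingness is added by
#' independent dropout. For each CpG and cell, coverage is negative binomial
#' (floored), the methylated count is Binomial(coverage, p), and p comes from
#' the cell's beta mixture, shifted by the planted effect size inside DMR
#' intervals targeting that cell. Proportions are clamped to [0.01, 0.99]
#' before the binomial draw.
#'
#' A per-site latent variable shared across cell types (Gaussian copula,
#' weight `site_rho`) is mapped through each cell's mixture quantile
#' function, so the marginal landscape of every cell is exactly its
#' specified beta mixture while methylomes correlate across cells the way
#' RRBS panels do; `site_rho = 1` makes the underlying proportions identical
#' across cells with the same spec (a strict per-site null), `site_rho = 0`
#' makes cells independent.
#'
#' @param genome a [genome_spec()].
#' @param per_cell_specs named list, cell type -> [methylome_spec()].
#' @param planted list of [planted_dmr()] objects.
#' @param dropout per-cell site dropout probability.
#' @param site_rho shared-landscape weight in [0, 1].
#' @return list with `methylomes` (named list of CpG record tables),
#'   `sites` (the shared site catalogue) and `manifest` (planted-DMR ground
#'   truth data.frame).
#' @export
simulate_methylomes <- function(genome, per_cell_specs, planted = list(),
                                dropout = 0.1, site_rho = 0.8) {
  if (site_rho < 0 || site_rho > 1) stop("site_rho must be in [0, 1]")
  stopifnot(inherits(genome, "genome_spec"))
  for (sp in per_cell_specs) stopifnot(inherits(sp, "methylome_spec"))
  for (p in planted) {
    stopifnot(inherits(p, "planted_dmr"))
    if (!p$chrom %in% names(genome$chrom_sizes)) {
      stop(sprintf("planted DMR on unknown chromosome %s", p$chrom))
    }
    if (p$end > genome$chrom_sizes[[p$chrom]]) {
      stop(sprintf("planted DMR [%d,%d) outside chromosome %s",
                   p$start, p$end, p$chrom))
    }
    if (!p$target_cell %in% names(per_cell_specs)) {
      stop(sprintf("planted DMR targets unknown cell %s", p$target_cell))
    }
  }
  with_seed(derive_seed(genome$seed, "methylomes"), {
    # shared site catalogue: guaranteed sites inside each planted interval,
    # the rest uniform over the chromosomes
    site_list <- lapply(planted, function(p) {
      pos <- sort(sample(seq.int(p$start, p$end - 1L), p$n_cpgs))
      data.frame(chrom = p$chrom, pos = pos, stringsAsFactors = FALSE)
    })
    n_rest <- max(0L, genome$n_cpgs - sum(vapply(planted, `[[`, integer(1), "n_cpgs")))
    w <- genome$chrom_sizes / sum(genome$chrom_sizes)
    per <- round_half_away(n_rest * w)
    rest <- do.call(rbind, lapply(seq_along(per), function(ci) {
      data.frame(chrom = names(genome$chrom_sizes)[ci],
                 pos = sample.int(genome$chrom_sizes[[ci]], per[ci]) - 1L,
                 stringsAsFactors = FALSE)
    }))
    sites <- rbind(do.call(rbind, site_list), rest)
    sites <- unique(sites[order(sites$chrom, sites$pos), , drop = FALSE])
    rownames(sites) <- NULL
    n <- nrow(sites)

    z_site <- rnorm(n)
    methylomes <- list()
    for (cell in names(per_cell_specs)) {
      spec <- per_cell_specs[[cell]]
      z <- sqrt(site_rho) * z_site + sqrt(1 - site_rho) * rnorm(n)
      p0 <- mixture_quantile(stats::pnorm(z), spec)
      for (pl in planted) {
        if (pl$target_cell != cell) next
        inside <- sites$chrom == pl$chrom & sites$pos >= pl$start &
          sites$pos < pl$end
        shift <- if (pl$direction == "hyper") pl$effect_size else -pl$effect_size
        p0[inside] <- p0[inside] + shift
      }
      p0 <- clamp(p0, 0.01, 0.99)
      cov <- pmax(spec$min_coverage_floor,
                  rnbinom(n, size = spec$coverage_dispersion,
                          mu = spec$coverage_mean))
      meth <- rbinom(n, cov, p0)
      keep <- runif(n) >= dropout
      methylomes[[cell]] <- cpg_records(
        chrom = sites$chrom[keep], pos = sites$pos[keep], strand = "+",
        coverage = cov[keep], meth_count = meth[keep]
      )
    }
    manifest <- if (length(planted) > 0) {
      do.call(rbind, lapply(planted, function(p) {
        data.frame(chrom = p$chrom, start = p$start, end = p$end,
                   target_cell = p$target_cell, direction = p$direction,
                   effect_size = p$effect_size, n_cpgs = p$n_cpgs,
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(chrom = character(), start = integer(), end = integer(),
                 target_cell = character(), direction = character(),
                 effect_size = numeric(), n_cpgs = integer())
    }
    list(methylomes = methylomes, sites = sites, manifest = manifest)
  })
}

canonical_segments <- c("gene body", "intron", "promoter", "5'UTR", "3'UTR", "CDS")

#' Simulate a differential-expression table from the linear methylation model
#'
#' Each gene's log2 fold change is generated as
#' `Methy * beta_methy + TSG * beta_tsg + beta_segment[segment] + eps`,
#' with Gaussian noise of standard deviation `sigma`. Methy is a signed mean
#' methylation difference in percentage points (hyper positive, hypo
#' negative); residuals are recorded so the generated table satisfies the
#' linear predictor identity exactly.
#'
#' @param n_per_segment named integer vector, segment -> gene count; names
#'   must be among `r paste(canonical_segments, collapse = ", ")`.
#' @param beta_methy,beta_tsg true coefficients.
#' @param beta_segment named numeric, per-segment true intercepts (defaults 0
#'   for any segment not named).
#' @param sigma residual standard deviation (> 0 unless exactly 0 for a
#'   noise-free table).
#' @param tsg_fraction probability a gene is flagged as a tumor suppressor.
#' @param methy_range absolute mean methylation difference range the signed
#'   Methy values are drawn from.
#' @param seed RNG seed.
#' @return list with `table` (data.frame gene, methy, tsg, segment, log2fc,
#'   residual) and `truth` (the coefficients, sigma and seed).
#' @export
simulate_expression <- function(n_per_segment, beta_methy = -0.02,
                                beta_tsg = 0.5, beta_segment = NULL,
                                sigma = 0.5, tsg_fraction = 0.3,
                                methy_range = c(20, 80), seed = 1L) {
  if (any(n_per_segment < 0)) stop("segment counts must be >= 0")
  if (sigma < 0) stop("sigma must be >= 0")
  unknown <- setdiff(names(n_per_segment), canonical_segments)
  if (length(unknown) > 0) {
    stop("unknown segment name(s): ", paste(unknown, collapse = ", "))
  }
  bs <- stats::setNames(rep(0, length(canonical_segments)), canonical_segments)
  if (!is.null(beta_segment)) {
    unknown <- setdiff(names(beta_segment), canonical_segments)
    if (length(unknown) > 0) {
      stop("unknown segment name(s): ", paste(unknown, collapse = ", "))
    }
    bs[names(beta_segment)] <- beta_segment
  }
  with_seed(derive_seed(seed, "expression"), {
    segment <- rep(names(n_per_segment), n_per_segment)
    n <- length(segment)
    methy <- sample(c(-1, 1), n, replace = TRUE) *
      runif(n, methy_range[1], methy_range[2])
    tsg <- runif(n) < tsg_fraction
    eps <- if (sigma > 0) rnorm(n, 0, sigma) else rep(0, n)
    log2fc <- methy * beta_methy + as.numeric(tsg) * beta_tsg +
      bs[segment] + eps
    tab <- data.frame(
      gene = sprintf("gene%05d", seq_len(n)),
      methy = methy, tsg = tsg, segment = segment,
      log2fc = as.numeric(log2fc), residual = eps,
      stringsAsFactors = FALSE
    )
    rownames(tab) <- NULL
    list(table = tab,
         truth = list(beta_methy = beta_methy, beta_tsg = beta_tsg,
                      beta_segment = bs, sigma = sigma, seed = seed))
  })
}

#' Write a simulated expression table as a DESeq-style TSV
#'
#' p-values are generated as two-sided normal tail probabilities of
#' log2fc / sigma_hat so that large fold changes get small p; BH-adjusted
#' padj included.
#'
#' @param sim result of [simulate_expression()].
#' @param path output path.
#' @export
write_expression_tsv <- function(sim, path) {
  tab <- sim$table
  s <- max(stats::sd(tab$log2fc), 1e-9)
  pval <- 2 * stats::pnorm(-abs(tab$log2fc) / s)
  dge <- data.frame(id = tab$gene, log2FoldChange = tab$log2fc,
                    pval = pval, padj = p.adjust(pval, "BH"),
                    stringsAsFactors = FALSE)
  write_dge_table(dge, path)
}

#' Simulate TF peak sets and promoter methylation per (cell, TF) combination
#'
#' Each combination either samples peak-covered promoters whose CpG
#' methylation follows the global background beta ("null-interplay") or a
#' shifted beta ("true-interplay"); a configurable fraction of combinations
#' emits no peaks at all ("no-data", exercising the null/gray class
#' downstream).
#'
#' @param promoters interval data.frame of promoter windows.
#' @param n_tfs,n_cells grid dimensions (cells are named cellA, cellB, ...;
#'   TFs TF01, ...).
#' @param fraction_shifted fraction of peak-bearing combinations drawn from
#'   the shifted beta.
#' @param shift_params c(alpha, beta) of the shifted component.
#' @param background_params c(alpha, beta) of the global background.
#' @param n_cpgs_per_combo methylation values measured per combination.
#' @param fraction_empty fraction of combinations with no peaks.
#' @param peaks_per_combo promoters bound per combination.
#' @param seed RNG seed.
#' @return list with `peaks` (named list "<cell>|<tf>" -> BED-style interval
#'   data.frame, absent for no-data combos), `values` (named list of
#'   methylation proportions) and `truth` (data.frame cell, tf, label).
#' @export
simulate_tf_peaks <- function(promoters, n_tfs = 5L, n_cells = 3L,
                              fraction_shifted = 0.15,
                              shift_params = c(1, 4),
                              background_params = c(2, 2),
                              n_cpgs_per_combo = 100L,
                              fraction_empty = 0.2,
                              peaks_per_combo = 5L, seed = 1L) {
  if (fraction_shifted < 0 || fraction_shifted > 1) {
    stop("fraction_shifted must be in [0, 1]")
  }
  if (fraction_empty < 0 || fraction_empty > 1) {
    stop("fraction_empty must be in [0, 1]")
  }
  with_seed(derive_seed(seed, "tf_peaks"), {
    cells <- paste0("cell", LETTERS[seq_len(n_cells)])
    tfs <- sprintf("TF%02d", seq_len(n_tfs))
    grid <- expand.grid(cell = cells, tf = tfs, stringsAsFactors = FALSE)
    n <- nrow(grid)
    u <- runif(n)
    label <- ifelse(u < fraction_empty, "no-data",
                    ifelse(runif(n) < fraction_shifted,
                           "true-interplay", "null-interplay"))
    peaks <- list()
    values <- list()
    for (i in seq_len(n)) {
      key <- paste(grid$cell[i], grid$tf[i], sep = "|")
      if (label[i] == "no-data") next
      idx <- sample.int(nrow(promoters), min(peaks_per_combo, nrow(promoters)))
      pk <- promoters[idx, c("chrom", "start", "end"), drop = FALSE]
      pk$name <- key
      pk$score <- 0
      pk$strand <- "."
      rownames(pk) <- NULL
      peaks[[key]] <- pk
      shp <- if (label[i] == "true-interplay") shift_params else background_params
      values[[key]] <- clamp(rbeta(n_cpgs_per_combo, shp[1], shp[2]),
                             0.01, 0.99)
    }
    truth <- cbind(grid, label = label, stringsAsFactors = FALSE)
    list(peaks = peaks, values = values, truth = truth)
  })
}

#' Write a flat key-value ground-truth manifest
#' @param truth named list of scalar values (vectors are comma-joined).
#' @param path output path.
#' @export
write_truth_manifest <- function(truth, path) {
  lines <- vapply(names(truth), function(k) {
    paste0(k, "\t", paste(truth[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
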