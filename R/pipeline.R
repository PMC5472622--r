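# End-to-end orchestration over a flat key-value config: synthetic data ->
# platform concordance -> DMC/DMR/cell-specific sets -> genomic regions ->
# Bayesian integration -> TF interplay. Each stage writes its artifacts and
# a small report; the manifest lists every file with an md5 checksum so a
# rerun under the same config and seed is verifiably identical.

pipeline_threshold_keys <- c(
  "min_coverage", "dmc_diff_min", "dmc_q_max", "dmr_diff_min",
  "dmr_q_candidate", "dmr_q_significant", "dmr_min_dmcs",
  "dge_lfc_min", "dge_padj_max", "ks_alpha"
)

#' Default pipeline configuration
#'
#' Thresholds default to the reference analysis settings: coverage >= 10
#' reads, DMC |difference| >= 25 points at q <= 0.01, DMR mean difference >=
#' 20 points at q <= 0.01 (significant tier q <= 0.001 with >= 5 DMCs), DGE
#' filter |log2FC| >= 0.2 at padj <= 0.05, and K-S adjusted-p threshold
#' 0.05. The MCMC schedule defaults to a simulation-sized 10,000 iterations
#' (1,000 burn-in); `mcmc_iterations = 5e5` reproduces the full reference
#' schedule.
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed; every stage derives its own stream from it.
#' @return named list of class "pipeline_config".
#' @export
default_pipeline_config <- function(out_dir = tempfile("methintegrate_run_"),
                                    seed = 1L) {
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    reference_cell = "cellA",
    n_cells = 3L,
    chrom_size = 400000L,
    n_cpgs = 4000L,
    n_genes = 24L,
    n_cgis = 14L,
    n_planted_dmrs = 6L,
    planted_effect_size = 0.4,
    min_coverage = 10L,
    dmc_diff_min = 25,
    dmc_q_max = 0.01,
    dmr_diff_min = 20,
    dmr_q_candidate = 0.01,
    dmr_q_significant = 0.001,
    dmr_min_dmcs = 5L,
    dge_lfc_min = 0.2,
    dge_padj_max = 0.05,
    ks_alpha = 0.05,
    ks_min_sites = 50L,
    mcmc_iterations = 10000L,
    mcmc_burn_in = 1000L,
    threads = 1L
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#' @param config a config list.
#' @return the config, invisibly; errors list every missing threshold key.
#' @export
validate_config <- function(config) {
  missing <- setdiff(pipeline_threshold_keys, names(config))
  if (length(missing) > 0) {
    stop("config is missing required threshold key(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(config)
}

#' Write / read a flat key-value config file
#'
#' One `key<TAB>value` line per entry; numeric values round-trip losslessly
#' (written with full precision), everything else as character.
#'
#' @param config config list.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    val <- if (is.numeric(v)) format(v, digits = 17, trim = TRUE)
    else as.character(v)
    paste0(k, "\t", val)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @return for `read_config`, the config list (numeric-looking values are
#'   converted back; integer-valued keys to integer).
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ref <- default_pipeline_config()
  out <- list()
  for (pt in parts) {
    k <- pt[1]
    v <- pt[2]
    num <- suppressWarnings(as.numeric(v))
    out[[k]] <- if (!is.na(num)) {
      if (k %in% names(ref) && is.integer(ref[[k]])) as.integer(num) else num
    } else v
  }
  class(out) <- "pipeline_config"
  out
}

pipeline_stages <- c("simulate", "concordance", "dmc", "dmr", "specific",
                     "regions", "integrate", "tfinterplay")

#' Names of the pipeline stages, in execution order
#' @return character vector.
#' @export
pipeline_stage_names <- function() pipeline_stages

#' Run one pipeline stage
#'
#' Stages run in the fixed order simulate, concordance, dmc, dmr, specific,
#' regions, integrate, tfinterplay; each consumes the state produced by the
#' previous ones (pass the `state` returned by the prior call) and appends
#' its artifacts and report.
#'
#' @param name stage name.
#' @param config pipeline config.
#' @param state accumulated state from earlier stages (NULL for simulate).
#' @return updated state; `state$reports[[name]]` holds the stage report.
#' @export
run_stage <- function(name, config, state = NULL) {
  validate_config(config)
  name <- match.arg(name, pipeline_stages)
  if (is.null(state)) state <- list(reports = list(), files = character())
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(fname) file.path(out_dir, fname)
  note_files <- function(...) state$files <<- unique(c(state$files, c(...)))

  if (name != "simulate" && is.null(state$sim)) {
    stop(sprintf("stage '%s' needs the simulate stage to run first", name))
  }

  if (name == "simulate") {
    genome <- genome_spec(c(chr1 = config$chrom_size),
                          n_genes = config$n_genes, n_cgis = config$n_cgis,
                          n_cpgs = config$n_cpgs, seed = config$seed)
    models <- simulate_gene_models(genome)
    cells <- paste0("cell", LETTERS[seq_len(config$n_cells)])
    specs <- stats::setNames(lapply(cells, function(cl) methylome_spec()), cells)
    span <- config$chrom_size %/% (config$n_planted_dmrs + 1)
    planted <- lapply(seq_len(config$n_planted_dmrs), function(i) {
      planted_dmr("chr1", (i - 1) * span + span %/% 2,
                  (i - 1) * span + span %/% 2 + 1000,
                  target_cell = config$reference_cell,
                  direction = if (i %% 2 == 0) "hyper" else "hypo",
                  effect_size = config$planted_effect_size, n_cpgs = 10L)
    })
    sim <- simulate_methylomes(genome, specs, planted)
    expr <- simulate_expression(
      n_per_segment = c("gene body" = 120L, intron = 120L, promoter = 120L,
                        "5'UTR" = 80L, CDS = 80L, "3'UTR" = 20L),
      seed = config$seed)
    proms <- promoter_windows(models$genes,
                              chrom_sizes = c(chr1 = config$chrom_size))
    tf <- simulate_tf_peaks(proms, n_tfs = 6L, n_cells = config$n_cells,
                            seed = config$seed)
    for (cl in cells) {
      write_methylkit_tsv(sim$methylomes[[cl]],
                          emit(sprintf("methylome_%s.tsv", cl)))
    }
    write_refflat(models$genes, emit("genes.refflat"))
    write_bed(models$cgis, emit("cgis.bed"))
    write_bed(cbind(sim$manifest[, c("chrom", "start", "end")],
                    name = sim$manifest$target_cell, score = 0,
                    strand = "."),
              emit("planted_dmrs.bed"))
    write_expression_tsv(expr, emit("dge.tsv"))
    state$sim <- sim
    state$models <- models
    state$expr <- expr
    state$tf <- tf
    state$cells <- cells
    note_files(emit(sprintf("methylome_%s.tsv", cells)), emit("genes.refflat"),
               emit("cgis.bed"), emit("planted_dmrs.bed"), emit("dge.tsv"))
    state$reports$simulate <- list(
      stage = "simulate", seed = config$seed, n_cells = length(cells),
      n_sites = nrow(state$sim$sites), n_planted = nrow(sim$manifest))
  } else if (name == "concordance") {
    mat <- pairwise_cell_matrix(state$sim$methylomes, config$min_coverage)
    utils::write.table(mat$values, emit("pairwise_correlation.tsv"),
                       sep = "\t", quote = FALSE)
    ref <- state$sim$methylomes[[config$reference_cell]]
    modality <- kde_modality(ref$meth_count[ref$coverage >= config$min_coverage] /
                               ref$coverage[ref$coverage >= config$min_coverage])
    note_files(emit("pairwise_correlation.tsv"))
    state$concordance <- list(matrix = mat, modality = modality)
    state$reports$concordance <- list(
      stage = "concordance", seed = config$seed,
      mean_offdiag_r = mean(mat$values[upper.tri(mat$values)]),
      reference_modality = modality$n_modes)
  } else if (name == "dmc") {
    # per-CpG calls for every unordered cell pair (sign: first minus second)
    pairs <- utils::combn(state$cells, 2, simplify = FALSE)
    state$dmcs <- stats::setNames(lapply(pairs, function(pr) {
      call_dmcs(state$sim$methylomes[[pr[1]]], state$sim$methylomes[[pr[2]]],
                config$min_coverage, config$dmc_diff_min, config$dmc_q_max)
    }), vapply(pairs, paste, character(1), collapse = "_vs_"))
    for (k in names(state$dmcs)) {
      utils::write.table(state$dmcs[[k]], emit(sprintf("dmcs_%s.tsv", k)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note_files(emit(sprintf("dmcs_%s.tsv", k)))
    }
    state$reports$dmc <- list(
      stage = "dmc", seed = config$seed,
      n_dmcs = vapply(state$dmcs, nrow, integer(1)))
  } else if (name == "dmr") {
    # A cell's DMR set is the consensus of its pairwise comparisons: regions
    # where it differs, with the same direction, from every other cell.
    pairs <- utils::combn(state$cells, 2, simplify = FALSE)
    pair_dmrs <- stats::setNames(lapply(pairs, function(pr) {
      key <- paste(pr, collapse = "_vs_")
      call_dmrs(state$dmcs[[key]], state$sim$methylomes[[pr[1]]],
                state$sim$methylomes[[pr[2]]], config$min_coverage,
                diff_min = config$dmr_diff_min,
                q_candidate = config$dmr_q_candidate,
                q_significant = config$dmr_q_significant,
                min_dmcs = config$dmr_min_dmcs)
    }), vapply(pairs, paste, character(1), collapse = "_vs_"))
    oriented <- function(cell, other) {
      key <- paste(cell, other, sep = "_vs_")
      if (key %in% names(pair_dmrs)) return(pair_dmrs[[key]])
      d <- pair_dmrs[[paste(other, cell, sep = "_vs_")]]
      d$mean_diff <- -d$mean_diff
      d$direction <- ifelse(d$direction == "hyper", "hypo", "hyper")
      d
    }
    sets <- list()
    for (cl in state$cells) {
      others <- setdiff(state$cells, cl)
      acc <- oriented(cl, others[1])
      for (o in others[-1]) {
        cmp <- oriented(cl, o)
        if (nrow(acc) == 0) break
        keep <- vapply(seq_len(nrow(acc)), function(i) {
          any(cmp$chrom == acc$chrom[i] & cmp$start < acc$end[i] &
                cmp$end > acc$start[i] & cmp$direction == acc$direction[i])
        }, logical(1))
        acc <- acc[keep, , drop = FALSE]
      }
      sets[[cl]] <- acc
      if (nrow(acc) > 0) {
        write_dmr_bed(acc, emit(sprintf("dmrs_%s.bed", cl)))
        note_files(emit(sprintf("dmrs_%s.bed", cl)))
      }
    }
    state$dmr_sets <- sets
    state$reports$dmr <- list(
      stage = "dmr", seed = config$seed,
      n_dmrs = vapply(sets, nrow, integer(1)))
  } else if (name == "specific") {
    spec <- cell_specific_subtraction(state$dmr_sets, config$reference_cell,
                                      tier = "significant")
    if (nrow(spec$dmrs) > 0) {
      write_dmr_bed(spec$dmrs, emit("cell_specific_dmrs.bed"))
      note_files(emit("cell_specific_dmrs.bed"))
    }
    if (nrow(spec$removed) > 0) {
      utils::write.table(spec$removed, emit("removed_dmrs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      note_files(emit("removed_dmrs.tsv"))
    }
    state$specific <- spec
    state$reports$specific <- list(
      stage = "specific", seed = config$seed,
      n_specific = nrow(spec$dmrs), n_removed = nrow(spec$removed))
  } else if (name == "regions") {
    part <- build_partition(state$models$cgis, state$models$genes,
                            chrom_sizes = c(chr1 = config$chrom_size))
    for (rn in c("CGI.NP", "CGIS.NP", "P.CGI", "P.CGIS", "P.NCGI", "P.NCGIS")) {
      if (nrow(part[[rn]]) > 0) {
        write_bed(part[[rn]], emit(sprintf("region_%s.bed", rn)))
        note_files(emit(sprintf("region_%s.bed", rn)))
      }
    }
    ref <- state$sim$methylomes[[config$reference_cell]]
    feats <- assign_features(ref, state$models$genes, state$models$cgis,
                             chrom_sizes = c(chr1 = config$chrom_size))
    profiles <- region_methylation_profiles(ref, part,
                                            min_coverage = config$min_coverage)
    state$partition <- part
    state$features <- feats
    state$reports$regions <- list(
      stage = "regions", seed = config$seed,
      gene_context = feats$fractions$gene_context,
      cpg_context = feats$fractions$cpg_context,
      profiled = vapply(profiles, `[[`, integer(1), "n"))
  } else if (name == "integrate") {
    design <- build_design(state$expr$table, min_n = 50L)
    fit <- gibbs_fit(design, iterations = config$mcmc_iterations,
                     burn_in = config$mcmc_burn_in,
                     seed = derive_seed(config$seed, "gibbs_base"))
    summ <- summarize_posterior(fit)
    utils::write.table(summ$summary, emit("posterior_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    design_h <- build_design(state$expr$table, min_n = 50L, hpro = TRUE)
    fit_h <- gibbs_fit(design_h, iterations = config$mcmc_iterations,
                       burn_in = config$mcmc_burn_in,
                       seed = derive_seed(config$seed, "gibbs_hpro"))
    cmp <- compare_models(list(base = fit, with_hpro = fit_h))
    utils::write.table(cmp, emit("model_comparison.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note_files(emit("posterior_summary.tsv"), emit("model_comparison.tsv"))
    state$fit <- fit
    state$comparison <- cmp
    state$reports$integrate <- list(
      stage = "integrate", seed = config$seed,
      n_rows = nrow(design$rows), dropped = design$dropped_segments,
      selection = stats::setNames(cmp$selection_probability, cmp$model))
  } else if (name == "tfinterplay") {
    values <- state$tf$values
    # add explicit empty entries for no-data combos so the grid is complete
    nodata <- state$tf$truth[state$tf$truth$label == "no-data", ]
    for (i in seq_len(nrow(nodata))) {
      values[[paste(nodata$cell[i], nodata$tf[i], sep = "|")]] <- numeric(0)
    }
    calls <- classify_interplay(values, min_sites = config$ks_min_sites,
                                alpha = config$ks_alpha)
    utils::write.table(as.data.frame(calls), emit("tf_interplay_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    grid <- interplay_class_grid(calls)
    utils::write.table(grid, emit("tf_interplay_grid.tsv"), sep = "\t",
                       quote = FALSE)
    note_files(emit("tf_interplay_calls.tsv"), emit("tf_interplay_grid.tsv"))
    state$interplay <- calls
    state$reports$tfinterplay <- list(
      stage = "tfinterplay", seed = config$seed,
      classes = table(calls$class))
  }
  state
}

#' Run the whole pipeline
#'
#' Executes every stage in order on the synthetic demo defined by the
#' config and returns the final state plus a manifest of all written files
#' with md5 checksums. Single-threaded by contract: results never depend on
#' `threads`.
#'
#' @param config pipeline config (see [default_pipeline_config()]).
#' @return state list; `state$manifest` is a data.frame (file, md5).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  validate_config(config)
  state <- NULL
  for (st in pipeline_stages) {
    state <- tryCatch(run_stage(st, config, state), error = function(e) {
      stop(sprintf("pipeline failed at stage '%s': %s", st, conditionMessage(e)))
    })
  }
  files <- sort(state$files[file.exists(state$files)])
  state$manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  utils::write.table(state$manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  state
}
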