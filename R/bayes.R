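# Bayesian Gaussian regression of differential expression (log2 fold
# change) on methylation, TSG status and genomic segment:
#
#   DGE_i = Methy_i * b_methy + TSG_i * b_tsg + b_segment(GS_i) + eps_i,
#   eps_i ~ N(0, sigma^2),
#
# with semi-conjugate priors beta ~ N(b0, B0^-1), sigma^-2 ~
# Gamma(c0/2, d0/2). The posterior is sampled by a two-block Gibbs sampler;
# the log marginal likelihood comes from the Chib single-point identity and
# models are compared by Bayes factor / posterior selection probability
# under equal prior odds.

#' Semi-conjugate prior specification
#'
#' @param p number of regression coefficients.
#' @param b0 prior mean vector (recycled scalar allowed).
#' @param B0 prior precision matrix, symmetric positive definite (a proper
#'   prior is required for the marginal likelihood); a scalar is expanded to
#'   a multiple of the identity.
#' @param c0,d0 Gamma hyperparameters: sigma^-2 ~ Gamma(c0/2, d0/2).
#' @return list of class "prior_spec".
#' @export
prior_spec <- function(p, b0 = 0, B0 = 1e-4, c0 = 0.002, d0 = 0.002) {
  b0 <- rep_len(b0, p)
  if (is.matrix(B0)) {
    if (!isTRUE(all.equal(B0, t(B0)))) stop("B0 must be symmetric")
    ev <- eigen(B0, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("B0 must be positive definite (proper prior)")
  } else {
    if (B0 <= 0) stop("B0 must be positive")
    B0 <- diag(B0, p)
  }
  if (c0 <= 0 || d0 <= 0) stop("c0 and d0 must be > 0")
  structure(list(b0 = b0, B0 = B0, c0 = c0, d0 = d0), class = "prior_spec")
}

#' Build the regression dataset and design matrix
#'
#' Rows are annotated genes with a hosting DMR: the design has one Methy
#' column (signed mean methylation difference of the hosting DMR, percentage
#' points), one TSG indicator, and one indicator per genomic segment
#' (cell-means coding, no global intercept) so each segment gets its own
#' coefficient. Segments with fewer than `min_n` rows are dropped and
#' recorded (the 3'UTR-style insufficiency dropout). An optional
#' differential-expression filter (|log2FC| >= 0.2, padj <= 0.05) may be
#' applied first via `dge_filter`.
#'
#' @param gene_table data.frame with columns gene, methy, tsg (logical),
#'   segment, log2fc (e.g. from [simulate_expression()] or
#'   [annotate_genes_to_dmrs()]).
#' @param min_n minimum rows per retained segment.
#' @param dge_filter optional list(lfc =, padj =) applied when the table has
#'   pval/padj columns.
#' @param hpro if TRUE add the binary HPRO column (1 = hyper, 0 = hypo,
#'   derived from sign(methy)); rows with methy == 0 are excluded.
#' @return list of class "regression_dataset": X, y, rows,
#'   coefficient_names, dropped_segments.
#' @export
build_design <- function(gene_table, min_n = 50L, dge_filter = NULL,
                         hpro = FALSE) {
  tab <- gene_table
  need <- c("gene", "methy", "tsg", "segment", "log2fc")
  if (!all(need %in% names(tab))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  }
  unknown <- setdiff(unique(tab$segment), canonical_segments)
  if (length(unknown) > 0) {
    stop("unknown segment name(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(dge_filter) && "padj" %in% names(tab)) {
    tab <- tab[abs(tab$log2fc) >= dge_filter$lfc & tab$padj <= dge_filter$padj, ,
               drop = FALSE]
  }
  if (hpro) tab <- tab[tab$methy != 0, , drop = FALSE]
  counts <- table(tab$segment)
  dropped <- names(counts)[counts < min_n]
  tab <- tab[!tab$segment %in% dropped, , drop = FALSE]
  if (nrow(tab) < 10) {
    stop(sprintf("refusing to fit: only %d rows retained (need >= 10)",
                 nrow(tab)))
  }
  segs <- sort(unique(tab$segment))
  X <- cbind(
    Methy = tab$methy,
    TSG = as.numeric(tab$tsg),
    vapply(segs, function(s) as.numeric(tab$segment == s),
           numeric(nrow(tab)))
  )
  colnames(X) <- c("Methy", "TSG", segs)
  if (hpro) {
    X <- cbind(X, HPRO = as.numeric(tab$methy > 0))
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  structure(list(X = X, y = tab$log2fc, rows = tab,
                 coefficient_names = colnames(X),
                 dropped_segments = dropped),
            class = "regression_dataset")
}

#' Annotate genes to hosting DMRs and segments for the regression
#'
#' Each gene is paired with the DMR overlapping its transcript-plus-promoter
#' extent; the hosting DMR is the one with the largest overlap (ties broken
#' by DMR order), and the gene's segment label is the segment (promoter,
#' 5'UTR, 3'UTR, CDS, intron, gene body) that the hosting DMR overlaps most,
#' ties broken alphabetically.
#'
#' @param dmrs DMR data.frame (chrom, start, end, mean_diff, direction).
#' @param genes gene-model data.frame.
#' @param dge differential-expression table (id, log2FoldChange, pval, padj).
#' @param tsg_ids TSG gene ids.
#' @param promoter_halfwidth promoter half-width, bp.
#' @return gene table suitable for [build_design()] (one row per gene with a
#'   hosting DMR and a DGE entry), with pval/padj carried through.
#' @export
annotate_genes_to_dmrs <- function(dmrs, genes, dge, tsg_ids,
                                   promoter_halfwidth = 1000L) {
  rows <- list()
  if (nrow(dmrs) > 0) {
    dmr_gr <- as_granges(dmrs)
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      segs <- derive_segments(g, promoter_halfwidth)
      ext <- genomic_intervals(
        g$chrom, min(g$tx_start, segs$promoter$start[1]),
        max(g$tx_end, segs$promoter$end[1]))
      hits <- which(IRanges::overlapsAny(dmr_gr, as_granges(ext),
                                         ignore.strand = TRUE))
      if (length(hits) == 0) next
      widths <- vapply(hits, function(d) {
        iv_bases(iv_intersect(dmrs[d, c("chrom", "start", "end")], ext))
      }, numeric(1))
      host <- hits[which.max(widths)]
      # segment the hosting DMR overlaps most, ties alphabetical
      seg_map <- c(promoter = "promoter", utr5 = "5'UTR", utr3 = "3'UTR",
                   cds = "CDS", intron = "intron", gene_body = "gene body")
      seg_cover <- vapply(names(seg_map), function(sk) {
        iv <- segs[[sk]]
        if (nrow(iv) == 0) return(0)
        iv_bases(iv_intersect(dmrs[host, c("chrom", "start", "end")], iv))
      }, numeric(1))
      if (all(seg_cover == 0)) next
      lab <- seg_map[names(seg_map)[seg_cover == max(seg_cover)]]
      lab <- sort(lab)[1]
      m <- match(g$gene_id, dge$id)
      if (is.na(m)) next
      rows[[length(rows) + 1]] <- data.frame(
        gene = g$gene_id, methy = dmrs$mean_diff[host],
        tsg = g$gene_id %in% tsg_ids, segment = unname(lab),
        log2fc = dge$log2FoldChange[m], pval = dge$pval[m],
        padj = dge$padj[m], dmr_id = host, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene = character(), methy = numeric(), tsg = logical(),
                      segment = character(), log2fc = numeric(),
                      pval = numeric(), padj = numeric(), dmr_id = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gibbs sampler for the semi-conjugate Gaussian regression
#'
#' Alternates the full conditionals: beta | sigma^2, y ~ Normal with
#' precision B0 + XtX / sigma^2 and mean solving (B0 + XtX/sigma^2) m =
#' B0 b0 + Xty / sigma^2; sigma^-2 | beta, y ~ Gamma((c0 + n)/2,
#' (d0 + ||y - X beta||^2)/2). The reference analysis schedule is 500,000
#' iterations with the first 1,000 discarded; smaller schedules are
#' adequate for the simulation studies shipped with the package.
#'
#' @param data a [build_design()] result.
#' @param prior a [prior_spec()]; default weak proper prior.
#' @param iterations total Gibbs iterations.
#' @param burn_in draws discarded from the front.
#' @param seed RNG seed (draws are reproducible under it).
#' @return list of class "posterior_draws": beta_draws (retained x p),
#'   sigma2_draws, burn_in, coefficient_names, data, prior, seed.
#' @export
gibbs_fit <- function(data, prior = NULL, iterations = 10000L,
                      burn_in = 1000L, seed = 1L) {
  stopifnot(inherits(data, "regression_dataset"))
  X <- data$X
  y <- data$y
  n <- length(y)
  p <- ncol(X)
  if (is.null(prior)) prior <- prior_spec(p)
  stopifnot(inherits(prior, "prior_spec"), length(prior$b0) == p)
  if (burn_in >= iterations) stop("burn_in must be < iterations")
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  B0b0 <- prior$B0 %*% prior$b0
  with_seed(seed, {
    sigma2 <- stats::var(y)
    if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1
    keep <- iterations - burn_in
    beta_draws <- matrix(NA_real_, keep, p,
                         dimnames = list(NULL, colnames(X)))
    sigma2_draws <- numeric(keep)
    for (it in seq_len(iterations)) {
      prec <- prior$B0 + XtX / sigma2
      R <- tryCatch(chol(prec), error = function(e) {
        stop(sprintf("non-positive-definite precision at iteration %d", it))
      })
      mean_b <- backsolve(R, forwardsolve(t(R), B0b0 + Xty / sigma2))
      beta <- mean_b + backsolve(R, rnorm(p))
      resid <- y - X %*% beta
      sigma2 <- 1 / rgamma(1, shape = (prior$c0 + n) / 2,
                           rate = (prior$d0 + sum(resid^2)) / 2)
      if (it > burn_in) {
        beta_draws[it - burn_in, ] <- beta
        sigma2_draws[it - burn_in] <- sigma2
      }
    }
    structure(list(beta_draws = beta_draws, sigma2_draws = sigma2_draws,
                   burn_in = burn_in, coefficient_names = colnames(X),
                   data = data, prior = prior, seed = seed),
              class = "posterior_draws")
  })
}

# log density of sigma2 when sigma^-2 ~ Gamma(shape, rate)
dinvgamma_log <- function(s2, shape, rate) {
  dgamma(1 / s2, shape = shape, rate = rate, log = TRUE) - 2 * log(s2)
}

#' Chib log marginal likelihood from Gibbs output
#'
#' Evaluates the single-point identity log m(y) = log p(y | beta*, sigma2*)
#' + log p(beta*) + log p(sigma2*) - log p(beta*, sigma2* | y) at the
#' posterior mean. The beta ordinate is Rao-Blackwellised over the retained
#' sigma2 draws; the sigma2 ordinate is its exact full conditional given
#' beta* (with two Gibbs blocks no reduced run is required).
#'
#' @param draws a [gibbs_fit()] result with >= 1,000 retained draws.
#' @return scalar log marginal likelihood (nats).
#' @export
log_marginal_likelihood <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  G <- nrow(draws$beta_draws)
  if (G < 1000) {
    stop(sprintf("need >= 1000 retained draws for a stable ordinate (have %d)",
                 G))
  }
  data <- draws$data
  prior <- draws$prior
  X <- data$X
  y <- data$y
  n <- length(y)
  p <- ncol(X)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  B0b0 <- prior$B0 %*% prior$b0
  beta_star <- colMeans(draws$beta_draws)
  sigma2_star <- mean(draws$sigma2_draws)
  resid_star <- y - X %*% beta_star
  log_lik <- sum(dnorm(y, X %*% beta_star, sqrt(sigma2_star), log = TRUE))
  # prior ordinates
  R0 <- chol(prior$B0)
  db <- beta_star - prior$b0
  log_prior_beta <- -p / 2 * log(2 * pi) + sum(log(diag(R0))) -
    0.5 * sum((R0 %*% db)^2)
  log_prior_sigma2 <- dinvgamma_log(sigma2_star, prior$c0 / 2, prior$d0 / 2)
  # posterior ordinate of beta*: average of N(beta* | m(s2_g), V(s2_g))
  ord_g <- vapply(draws$sigma2_draws, function(s2) {
    prec <- prior$B0 + XtX / s2
    R <- chol(prec)
    m <- backsolve(R, forwardsolve(t(R), B0b0 + Xty / s2))
    -p / 2 * log(2 * pi) + sum(log(diag(R))) -
      0.5 * sum((R %*% (beta_star - m))^2)
  }, numeric(1))
  log_post_beta <- logsumexp(ord_g) - log(G)
  # posterior ordinate of sigma2* | beta*, y: exact full conditional
  log_post_sigma2 <- dinvgamma_log(
    sigma2_star, (prior$c0 + n) / 2, (prior$d0 + sum(resid_star^2)) / 2)
  log_lik + log_prior_beta + log_prior_sigma2 -
    log_post_beta - log_post_sigma2
}

#' Posterior selection probabilities from log marginal likelihoods
#'
#' Under equal prior odds, the probability of model k is exp(LML_k) /
#' sum_j exp(LML_j), computed stably through log-sum-exp.
#'
#' @param lml numeric vector of log marginal likelihoods (optionally named).
#' @return probabilities summing to 1.
#' @export
model_selection_probability <- function(lml) {
  if (length(lml) == 0) stop("need at least one log marginal likelihood")
  exp(lml - logsumexp(lml))
}

#' Compare the base regression model with a variant by Bayes factor
#'
#' Both models must be fitted on identical rows (the comparison is invalid
#' otherwise). The canonical use is base (Methy + TSG + segments) against
#' base + HPRO, the binary hyper/hypo indicator whose information is already
#' carried by the sign of Methy.
#'
#' @param fits named list of [gibbs_fit()] results.
#' @return data.frame of class "model_comparison": model, log_marginal
#'   likelihood, selection_probability (equal prior odds).
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2, !is.null(names(fits)))
  g0 <- fits[[1]]$data$rows$gene
  for (f in fits[-1]) {
    if (!identical(f$data$rows$gene, g0)) {
      stop("models are fitted on different row sets; comparison invalid")
    }
  }
  lml <- vapply(fits, log_marginal_likelihood, numeric(1))
  out <- data.frame(model = names(fits), log_marginal_likelihood = lml,
                    selection_probability = model_selection_probability(lml),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Posterior summaries: median and 95% central interval per coefficient
#'
#' @param draws a [gibbs_fit()] result.
#' @param thin keep every `thin`-th draw in the returned trace (for plots).
#' @return list with `summary` (data.frame coefficient, median, lo, hi) and
#'   `trace` (thinned draws).
#' @export
summarize_posterior <- function(draws, thin = 10L) {
  stopifnot(inherits(draws, "posterior_draws"))
  b <- draws$beta_draws
  if (nrow(b) == 0) stop("no retained draws")
  qs <- apply(b, 2, quantile, probs = c(0.025, 0.5, 0.975))
  s2q <- quantile(draws$sigma2_draws, probs = c(0.025, 0.5, 0.975))
  summary <- data.frame(
    coefficient = c(colnames(b), "sigma2"),
    median = c(qs[2, ], s2q[2]),
    lo = c(qs[1, ], s2q[1]),
    hi = c(qs[3, ], s2q[3]),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  idx <- seq(1, nrow(b), by = thin)
  list(summary = summary,
       trace = cbind(b[idx, , drop = FALSE], sigma2 = draws$sigma2_draws[idx]))
}
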