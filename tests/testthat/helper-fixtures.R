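# Shared fixture builders and independent oracles for the test suite.
# Oracles are deliberately implemented by a different route than the package
# code they check (brute-force enumeration, numerical quadrature).

# small methylome table from parallel vectors
make_methylome <- function(pos, coverage, meth, chrom = "chr1") {
  cpg_records(chrom = rep(chrom, length(pos)), pos = pos,
              strand = "+", coverage = coverage, meth_count = meth)
}

# Brute-force two-sided Fisher p for a 2x2 table with fixed margins, by
# direct enumeration of choose() products (no dhyper): reference oracle.
fisher_oracle <- function(m1, c1, m2, c2) {
  k <- m1 + m2
  lo <- max(0, k - c2)
  hi <- min(c1, k)
  supp <- lo:hi
  w <- choose(c1, supp) * choose(c2, k - supp)
  prob <- w / sum(w)
  p0 <- prob[m1 - lo + 1]
  sum(prob[prob <= p0 * (1 + 1e-7)])
}

# 2-D numerical quadrature of the marginal likelihood for a one-predictor
# Gaussian regression with N(b0, 1/B0) prior on beta and
# sigma^-2 ~ Gamma(c0/2, d0/2): log m(y) = log int int p(y|b,s2) p(b) p(s2).
lml_quadrature <- function(y, x, b0, B0, c0, d0) {
  n <- length(y)
  log_joint <- function(b, s2) {
    sum(dnorm(y, x * b, sqrt(s2), log = TRUE)) +
      dnorm(b, b0, sqrt(1 / B0), log = TRUE) +
      dgamma(1 / s2, shape = c0 / 2, rate = d0 / 2, log = TRUE) - 2 * log(s2)
  }
  # locate the mode roughly to set an underflow shift
  bh <- sum(x * y) / sum(x * x)
  s2h <- max(mean((y - x * bh)^2), 1e-3)
  shift <- log_joint(bh, s2h)
  inner <- function(s2) {
    vapply(s2, function(s) {
      stats::integrate(function(b) {
        vapply(b, function(bi) exp(log_joint(bi, s) - shift), numeric(1))
      }, lower = bh - 30, upper = bh + 30, rel.tol = 1e-9)$value
    }, numeric(1))
  }
  out <- stats::integrate(inner, lower = 1e-4, upper = 200,
                          rel.tol = 1e-8, subdivisions = 400L)
  log(out$value) + shift
}

# standard planted-DMR recovery study: two cells with a tight unimodal
# baseline sharing the per-site landscape exactly (site_rho = 1), hyper and
# hypo DMRs planted in the first cell; returns per-replicate recovery flags
run_recovery_replicate <- function(seed, effect = 0.4, coverage = 30,
                                   n_cpgs = 8L, n_dmrs = 6L) {
  gs <- genome_spec(c(chr1 = 100000L), n_cpgs = 1200L, seed = seed)
  spec <- methylome_spec("unimodal", component_params = list(c(10, 10)),
                         coverage_mean = coverage)
  span <- 100000L %/% (n_dmrs + 1)
  planted <- lapply(seq_len(n_dmrs), function(i) {
    planted_dmr("chr1", (i - 1) * span + span %/% 2,
                (i - 1) * span + span %/% 2 + 800L,
                target_cell = "target",
                direction = if (i %% 2 == 0) "hyper" else "hypo",
                effect_size = effect, n_cpgs = n_cpgs)
  })
  sim <- simulate_methylomes(gs, list(target = spec, other = spec),
                             planted, dropout = 0, site_rho = 1)
  dmcs <- call_dmcs(sim$methylomes$target, sim$methylomes$other)
  dmrs <- call_dmrs(dmcs, sim$methylomes$target, sim$methylomes$other)
  vapply(seq_len(nrow(sim$manifest)), function(i) {
    p <- sim$manifest[i, ]
    any(dmrs$chrom == p$chrom & dmrs$start < p$end & dmrs$end > p$start &
          dmrs$direction == p$direction)
  }, logical(1))
}

# random non-degenerate interval set on one chromosome
random_interval_set <- function(n, max_pos = 10000L) {
  s <- sort(sample.int(max_pos, n))
  w <- sample(10:400, n, replace = TRUE)
  genomic_intervals(rep("chr1", n), s, s + w)
}

# dress an interval set up as a DMR table
toy_dmrs_from <- function(iv, direction = "hyper") {
  data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
             mean_diff = 30, p_value = 1e-5, q_value = 1e-4, n_dmcs = 6L,
             direction = direction, tier = "significant",
             stringsAsFactors = FALSE)
}
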