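sim_design <- function(n = 200, seed = 1, sigma = 0.5, hpro = FALSE,
                       min_n = 10L) {
  sim <- simulate_expression(
    c(promoter = n %/% 2, CDS = n - n %/% 2),
    beta_methy = -0.02, beta_tsg = 0.5,
    beta_segment = c(promoter = 0.3, CDS = -0.2), sigma = sigma, seed = seed)
  build_design(sim$table, min_n = min_n, hpro = hpro)
}

test_that("design rows encode Methy, TSG and segment indicators", {
  set.seed(1)
  tab <- data.frame(gene = paste0("g", 1:20),
                    methy = c(30, round(rnorm(19, 0, 25), 1)),
                    tsg = c(TRUE, rep(FALSE, 19)),
                    segment = c("promoter", rep("CDS", 9),
                                rep("promoter", 10)),
                    log2fc = rnorm(20), stringsAsFactors = FALSE)
  d <- build_design(tab, min_n = 5L)
  expect_equal(colnames(d$X), c("Methy", "TSG", "CDS", "promoter"))
  expect_equal(unname(d$X[1, ]), c(30, 1, 0, 1))
  expect_equal(unname(d$X[2, ]), c(tab$methy[2], 0, 1, 0))
})

test_that("sparse segments are dropped and recorded", {
  sim <- simulate_expression(c(promoter = 100L, "3'UTR" = 25L), seed = 3)
  d <- build_design(sim$table, min_n = 50L)
  expect_equal(d$dropped_segments, "3'UTR")
  expect_equal(nrow(d$rows), 100)
  expect_false("3'UTR" %in% colnames(d$X))
})

test_that("degenerate designs are caught", {
  sim <- simulate_expression(c(promoter = 12L), seed = 5)
  d <- build_design(sim$table, min_n = 5L)
  expect_equal(qr(d$X)$rank, ncol(d$X))  # single segment still full rank
  small <- simulate_expression(c(promoter = 8L), seed = 5)
  expect_error(build_design(small$table, min_n = 1L), "refusing to fit")
  bad <- sim$table
  bad$segment <- "enhancer"
  expect_error(build_design(bad, min_n = 1L), "unknown segment")
})

test_that("Gibbs draws are reproducible under a seed", {
  d <- sim_design(n = 60, seed = 2)
  f1 <- gibbs_fit(d, iterations = 500, burn_in = 100, seed = 7)
  f2 <- gibbs_fit(d, iterations = 500, burn_in = 100, seed = 7)
  expect_identical(f1$beta_draws, f2$beta_draws)
  expect_identical(f1$sigma2_draws, f2$sigma2_draws)
  expect_true(all(f1$sigma2_draws > 0))
  expect_equal(nrow(f1$beta_draws), 400)
})

test_that("an overwhelming prior pins the posterior at its mean", {
  d <- sim_design(n = 40, seed = 4)
  p <- ncol(d$X)
  prior <- prior_spec(p, b0 = 3, B0 = diag(1e12, p))
  fit <- gibbs_fit(d, prior, iterations = 2000, burn_in = 500, seed = 1)
  med <- apply(fit$beta_draws, 2, median)
  expect_true(all(abs(med - 3) < 0.01))
})

test_that("with sigma2 pinned the draws match the conjugate closed form", {
  d <- sim_design(n = 150, seed = 6)
  p <- ncol(d$X)
  s2 <- 0.25
  # c0, d0 huge with d0/c0 = s2 freezes the variance at s2
  prior <- prior_spec(p, b0 = 0, B0 = diag(1e-2, p),
                      c0 = 1e8, d0 = 1e8 * s2)
  fit <- gibbs_fit(d, prior, iterations = 11000, burn_in = 1000, seed = 3)
  prec <- prior$B0 + crossprod(d$X) / s2
  V <- solve(prec)
  m <- V %*% (prior$B0 %*% prior$b0 + crossprod(d$X, d$y) / s2)
  for (j in c(1, 2)) {
    ks <- suppressWarnings(
      stats::ks.test(fit$beta_draws[, j], "pnorm", m[j], sqrt(V[j, j])))
    expect_lt(unname(ks$statistic), 0.05)
  }
})

test_that("posterior summaries follow percentile arithmetic", {
  fake <- structure(list(
    beta_draws = cbind(b = rep(2, 50)), sigma2_draws = rep(1, 50),
    burn_in = 0L, coefficient_names = "b"), class = "posterior_draws")
  s <- summarize_posterior(fake, thin = 1L)
  expect_equal(s$summary$median[1], 2)
  expect_equal(s$summary$lo[1], 2)
  expect_equal(s$summary$hi[1], 2)

  fake$beta_draws <- cbind(b = as.numeric(1:100))
  fake$sigma2_draws <- rep(1, 100)
  s <- summarize_posterior(fake, thin = 1L)
  expect_equal(s$summary$median[1], 50.5)
  expect_equal(s$summary$lo[1], 3.475)
  expect_equal(s$summary$hi[1], 97.525)

  perm <- fake
  perm$beta_draws <- cbind(b = as.numeric(sample(100)))
  expect_equal(summarize_posterior(perm, thin = 1L)$summary,
               s$summary)
})

test_that("selection probabilities are stable and normalized", {
  expect_equal(model_selection_probability(c(-5, -5)), c(0.5, 0.5))
  p <- model_selection_probability(c(-1335.051, -1339.274))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # no underflow at |LML| ~ 1e3
  expect_true(all(is.finite(p)))
  huge <- model_selection_probability(c(-1e3, -2e3, -3e3))
  expect_equal(sum(huge), 1, tolerance = 1e-12)
})

test_that("model comparison refuses mismatched row sets", {
  d1 <- sim_design(n = 60, seed = 2)
  d2 <- sim_design(n = 62, seed = 3)
  f1 <- gibbs_fit(d1, iterations = 2100, burn_in = 100, seed = 1)
  f2 <- gibbs_fit(d2, iterations = 2100, burn_in = 100, seed = 1)
  expect_error(compare_models(list(a = f1, b = f2)), "different row sets")
})

test_that("the Chib estimate matches quadrature on a tiny problem", {
  y <- c(0.3, -0.2, 0.9, 0.4)
  X <- cbind(Methy = c(1, 2, -1, 0.5))
  d <- structure(list(X = X, y = y,
                      rows = data.frame(gene = paste0("g", 1:4)),
                      coefficient_names = "Methy",
                      dropped_segments = character(0)),
                 class = "regression_dataset")
  prior <- prior_spec(1, b0 = 0, B0 = 1, c0 = 2, d0 = 2)
  oracle <- lml_quadrature(y, X[, 1], b0 = 0, B0 = 1, c0 = 2, d0 = 2)
  fit <- gibbs_fit(d, prior, iterations = 6000, burn_in = 1000, seed = 11)
  expect_lt(abs(log_marginal_likelihood(fit) - oracle), 0.05)
  # determinism
  fit2 <- gibbs_fit(d, prior, iterations = 6000, burn_in = 1000, seed = 11)
  expect_identical(log_marginal_likelihood(fit),
                   log_marginal_likelihood(fit2))
  short <- gibbs_fit(d, prior, iterations = 1200, burn_in = 1000, seed = 1)
  expect_error(log_marginal_likelihood(short), "1000 retained")
})

test_that("consistent rescaling of data and prior preserves the Bayes factor", {
  d_base <- sim_design(n = 120, seed = 8)
  d_var <- sim_design(n = 120, seed = 8, hpro = TRUE)
  p1 <- ncol(d_base$X)
  p2 <- ncol(d_var$X)
  fit <- function(d, prior, seed) {
    gibbs_fit(d, prior, iterations = 4000, burn_in = 1000, seed = seed)
  }
  bf <- function(scale) {
    pr <- function(p) prior_spec(p, b0 = 0, B0 = diag(1e-4 / scale^2, p),
                                 c0 = 0.02, d0 = 0.02 * scale^2)
    db <- d_base; dv <- d_var
    db$y <- db$y * scale
    dv$y <- dv$y * scale
    log_marginal_likelihood(fit(db, pr(p1), 5)) -
      log_marginal_likelihood(fit(dv, pr(p2), 6))
  }
  expect_lt(abs(bf(1) - bf(2)), 0.3)
})
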