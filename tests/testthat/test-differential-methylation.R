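test_that("Fisher p matches the closed 9/1-vs-1/9 enumeration", {
  # margins 10/10 with 10 methylated overall: the two-sided tail is
  # {9,10,1,0} with weight (100 + 1) * 2 = 202 out of C(20,10)
  p <- fisher_test_counts(9L, 10L, 1L, 10L)
  expect_equal(p, 202 / 184756, tolerance = 1e-12)
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(5)
  c1 <- sample(5:60, 200, replace = TRUE)
  c2 <- sample(5:60, 200, replace = TRUE)
  m1 <- vapply(c1, function(n) sample.int(n + 1L, 1L) - 1L, integer(1))
  m2 <- vapply(c2, function(n) sample.int(n + 1L, 1L) - 1L, integer(1))
  ours <- fisher_test_counts(m1, c1, m2, c2)
  ref <- mapply(function(a, b, c, d) {
    stats::fisher.test(matrix(c(a, b - a, c, d - c), 2, byrow = TRUE))$p.value
  }, m1, c1, m2, c2)
  expect_equal(ours, unname(ref), tolerance = 1e-12)
})

test_that("DMC calling applies coverage, difference and q filters", {
  # site 1: strong difference; site 2: identical counts; site 3: low coverage
  ref <- make_methylome(pos = c(100L, 200L, 300L),
                        coverage = c(40L, 30L, 9L),
                        meth = c(36L, 15L, 9L))
  oth <- make_methylome(pos = c(100L, 200L, 300L),
                        coverage = c(40L, 30L, 50L),
                        meth = c(4L, 15L, 0L))
  dmcs <- call_dmcs(ref, oth)
  expect_equal(attr(dmcs, "n_tested"), 2L)  # low-coverage site excluded
  expect_equal(nrow(dmcs), 1)
  expect_equal(dmcs$pos, 100L)
  expect_equal(dmcs$meth_diff, 80)
  expect_equal(dmcs$direction, "hyper")
})

test_that("empty shared catalogue warns and returns an empty set", {
  a <- make_methylome(pos = 1L, coverage = 30L, meth = 10L)
  b <- make_methylome(pos = 999L, coverage = 30L, meth = 10L)
  expect_warning(d <- call_dmcs(a, b), "no shared sites")
  expect_equal(nrow(d), 0)
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(numeric(0)), numeric(0))
  expect_error(benjamini_hochberg(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("window pooling computes the mean difference from pooled counts", {
  ref <- make_methylome(pos = c(100L, 600L), coverage = c(10L, 10L),
                        meth = c(8L, 9L))
  oth <- make_methylome(pos = c(100L, 600L), coverage = c(10L, 10L),
                        meth = c(2L, 1L))
  dmcs <- call_dmcs(ref, oth)
  dmrs <- call_dmrs(dmcs, ref, oth)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$mean_diff, 70)  # 85% - 15%
  expect_equal(dmrs$direction, "hyper")
  expect_error(call_dmrs(dmcs, ref, oth, window = 0), "> 0")
})

test_that("the significant tier needs both q <= 0.001 and >= 5 DMCs", {
  build <- function(n_cpgs) {
    pos <- seq(10L, by = 50L, length.out = n_cpgs)
    ref <- make_methylome(pos = pos, coverage = rep(60L, n_cpgs),
                          meth = rep(54L, n_cpgs))
    oth <- make_methylome(pos = pos, coverage = rep(60L, n_cpgs),
                          meth = rep(6L, n_cpgs))
    dmcs <- call_dmcs(ref, oth)
    list(dmrs = call_dmrs(dmcs, ref, oth), n_dmcs = nrow(dmcs))
  }
  six <- build(6L)
  expect_equal(six$n_dmcs, 6L)
  expect_equal(six$dmrs$tier, "significant")
  four <- build(4L)
  expect_equal(four$dmrs$n_dmcs, 4L)
  expect_equal(four$dmrs$tier, "candidate")  # q tiny but too few DMCs
})

test_that("adjacent same-direction windows merge into one DMR", {
  pos <- c(100L, 600L, 1100L, 1600L)  # two adjacent 1 kb windows
  ref <- make_methylome(pos = pos, coverage = rep(50L, 4),
                        meth = rep(45L, 4))
  oth <- make_methylome(pos = pos, coverage = rep(50L, 4),
                        meth = rep(5L, 4))
  dmcs <- call_dmcs(ref, oth)
  dmrs <- call_dmrs(dmcs, ref, oth)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$start, 0L)
  expect_equal(dmrs$end, 2000L)
  expect_equal(dmrs$mean_diff, 80)
  expect_equal(dmrs$n_dmcs, 4L)
})

test_that("opposite-direction neighbours stay separate", {
  pos <- c(100L, 1100L)
  ref <- make_methylome(pos = pos, coverage = c(50L, 50L),
                        meth = c(45L, 5L))
  oth <- make_methylome(pos = pos, coverage = c(50L, 50L),
                        meth = c(5L, 45L))
  dmrs <- call_dmrs(call_dmcs(ref, oth), ref, oth)
  expect_equal(nrow(dmrs), 2)
  expect_setequal(dmrs$direction, c("hyper", "hypo"))
})

toy_dmrs <- function(starts, ends, direction = "hyper") {
  data.frame(chrom = "chr1", start = starts, end = ends,
             mean_diff = 30, p_value = 1e-5, q_value = 1e-4,
             n_dmcs = 6L, direction = direction, tier = "significant",
             stringsAsFactors = FALSE)
}

test_that("set deduction removes any-overlap DMRs and keeps abutting ones", {
  sets <- list(
    refcell = toy_dmrs(c(100L, 300L), c(200L, 400L)),
    other = toy_dmrs(150L, 160L, "hypo")
  )
  out <- cell_specific_subtraction(sets, "refcell")
  expect_equal(out$dmrs$start, 300L)
  expect_equal(out$removed$start, 100L)
  expect_equal(out$removed$blocking_cell, "other")

  # exact abutment shares no base under half-open semantics
  sets <- list(refcell = toy_dmrs(100L, 200L),
               other = toy_dmrs(200L, 300L))
  out <- cell_specific_subtraction(sets, "refcell")
  expect_equal(nrow(out$dmrs), 1)
  expect_equal(nrow(out$removed), 0)
})

test_that("deduction with only the reference present is the identity", {
  sets <- list(solo = toy_dmrs(c(1L, 50L), c(10L, 80L)))
  out <- cell_specific_subtraction(sets, "solo")
  expect_equal(out$dmrs, sets$solo)
  expect_error(cell_specific_subtraction(sets, "ghost"), "missing")
})

test_that("deduction is idempotent on random interval sets", {
  set.seed(99)
  for (rep in 1:20) {
    sets <- list(a = toy_dmrs_from(random_interval_set(15)),
                 b = toy_dmrs_from(random_interval_set(10)),
                 c = toy_dmrs_from(random_interval_set(12)))
    once <- cell_specific_subtraction(sets, "a")
    sets2 <- sets
    sets2$a <- once$dmrs
    twice <- cell_specific_subtraction(sets2, "a")
    expect_equal(twice$dmrs, once$dmrs, ignore_attr = TRUE)
    expect_equal(nrow(twice$removed), 0)
  }
})
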