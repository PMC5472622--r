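test_that("the six-region partition reproduces the worked interval layout", {
  # TSS at 10,000 on +: promoter [9000,11000); CGI [10500,10800);
  # shores [9500,10500) and [10800,11800)
  genes <- data.frame(gene_id = "g1", tx_id = "t1", chrom = "chr1",
                      strand = "+", tx_start = 10000L, tx_end = 15000L,
                      cds_start = 10000L, cds_end = 15000L,
                      stringsAsFactors = FALSE)
  genes$exon_starts <- list(10000L)
  genes$exon_ends <- list(15000L)
  cgis <- genomic_intervals("chr1", 10500L, 10800L)
  part <- build_partition(cgis, genes)
  iv <- function(x) unname(as.matrix(x[, c("start", "end")]))
  expect_equal(nrow(part$CGI.NP), 0)
  expect_equal(iv(part$CGIS.NP), rbind(c(11000L, 11800L)))
  expect_equal(iv(part$P.CGI), rbind(c(10500L, 10800L)))
  expect_equal(iv(part$P.CGIS), rbind(c(9500L, 10500L), c(10800L, 11000L)))
  expect_equal(iv(part$P.NCGI), rbind(c(9000L, 10500L), c(10800L, 11000L)))
  expect_equal(iv(part$P.NCGIS), rbind(c(9000L, 9500L)))
})

test_that("no islands collapses the partition onto promoters", {
  genes <- data.frame(gene_id = "g1", tx_id = "t1", chrom = "chr1",
                      strand = "+", tx_start = 5000L, tx_end = 8000L,
                      cds_start = 5000L, cds_end = 8000L,
                      stringsAsFactors = FALSE)
  genes$exon_starts <- list(5000L)
  genes$exon_ends <- list(8000L)
  part <- build_partition(genomic_intervals(character(), integer(), integer()),
                          genes)
  expect_equal(nrow(part$CGI.NP), 0)
  expect_equal(nrow(part$CGIS.NP), 0)
  expect_equal(nrow(part$P.CGI), 0)
  expect_equal(nrow(part$P.CGIS), 0)
  expect_equal(part$P.NCGI[, c("start", "end")],
               data.frame(start = 4000L, end = 6000L))
  expect_equal(part$P.NCGIS, part$P.NCGI)
})

check_partition_identities <- function(part) {
  bases <- methintegrate:::iv_bases
  union2 <- methintegrate:::iv_union
  intersect2 <- methintegrate:::iv_intersect
  # V + III tile the promoters; I + III tile the islands; II avoids islands
  expect_equal(bases(union2(part$P.NCGI, part$P.CGI)), bases(part$promoter))
  expect_equal(bases(intersect2(part$P.NCGI, part$P.CGI)), 0L)
  expect_equal(bases(union2(part$CGI.NP, part$P.CGI)), bases(part$cgi))
  expect_equal(bases(intersect2(part$CGIS.NP, part$cgi)), 0L)
}

test_that("base-set identities hold on randomized layouts", {
  set.seed(71)
  for (rep in 1:50) {
    n <- sample(3:10, 1)
    tx_s <- sort(sample.int(80000L, n)) + 2000L
    genes <- data.frame(gene_id = paste0("g", seq_len(n)),
                        tx_id = paste0("t", seq_len(n)), chrom = "chr1",
                        strand = sample(c("+", "-"), n, replace = TRUE),
                        tx_start = tx_s, tx_end = tx_s + 3000L,
                        cds_start = tx_s, cds_end = tx_s + 3000L,
                        stringsAsFactors = FALSE)
    genes$exon_starts <- as.list(tx_s)
    genes$exon_ends <- as.list(tx_s + 3000L)
    cgis <- random_interval_set(sample(2:8, 1), max_pos = 90000L)
    part <- build_partition(cgis, genes)
    check_partition_identities(part)
  }
})

test_that("partition does not depend on input interval order", {
  set.seed(8)
  genes <- data.frame(gene_id = c("a", "b"), tx_id = c("a", "b"),
                      chrom = "chr1", strand = "+",
                      tx_start = c(10000L, 11000L), tx_end = c(14000L, 15000L),
                      cds_start = c(10000L, 11000L), cds_end = c(14000L, 15000L),
                      stringsAsFactors = FALSE)
  genes$exon_starts <- list(10000L, 11000L)
  genes$exon_ends <- list(14000L, 15000L)
  cgis <- random_interval_set(6, 20000L)
  p1 <- build_partition(cgis, genes)
  p2 <- build_partition(cgis[sample(nrow(cgis)), ], genes[2:1, ])
  expect_equal(p1, p2)
  # overlapping promoters merge; identities still hold
  check_partition_identities(p1)
})

feature_fixture <- function() {
  genes <- data.frame(gene_id = "g1", tx_id = "t1", chrom = "chr1",
                      strand = "+", tx_start = 2000L, tx_end = 8000L,
                      cds_start = 2000L, cds_end = 8000L,
                      stringsAsFactors = FALSE)
  genes$exon_starts <- list(c(2000L, 6000L))
  genes$exon_ends <- list(c(4000L, 8000L))
  genes
}

test_that("feature assignment applies the precedence rules", {
  genes <- feature_fixture()
  cgis <- genomic_intervals("chr1", 2500L, 2600L)
  sites <- data.frame(chrom = "chr1",
                      pos = c(2500L,   # promoter AND exon -> promoter
                              5000L,   # intron
                              6500L,   # exon
                              20000L)) # nothing
  out <- assign_features(sites, genes, cgis)
  expect_equal(out$assignments$gene_context,
               c("promoter", "intron", "exon", "intergenic"))
  expect_equal(out$assignments$cpg_context,
               c("CGI", "open sea", "open sea", "open sea"))
})

test_that("feature fractions count sites per label", {
  genes <- feature_fixture()
  cgis <- genomic_intervals(character(), integer(), integer())
  sites <- data.frame(
    chrom = "chr1",
    pos = c(sample(1000:2999, 40, replace = TRUE),       # promoter
            sample(20000:30000, 60, replace = TRUE)))    # intergenic
  out <- assign_features(sites, genes, cgis)
  expect_equal(unname(out$fractions$gene_context["promoter"]), 0.40)
  expect_equal(unname(out$fractions$gene_context["intergenic"]), 0.60)
  expect_equal(sum(out$fractions$gene_context), 1)
})

test_that("region profiles conserve counts and flag empty regions", {
  genes <- feature_fixture()
  cgis <- genomic_intervals("chr1", 10000L, 11000L)  # far from promoter
  part <- build_partition(cgis, genes)
  m <- make_methylome(pos = c(seq(10100L, 10900L, by = 100L)),
                      coverage = rep(50L, 9), meth = rep(0L, 9))
  prof <- region_methylation_profiles(m, part)
  expect_equal(prof$CGI.NP$n, 9L)
  expect_equal(sum(prof$CGI.NP$counts), 9L)
  expect_equal(prof$CGI.NP$counts[1], 9L)  # uniformly unmethylated
  expect_true(prof$P.CGI$empty)
})

test_that("hyper islands and hypo promoters separate in the profiles", {
  set.seed(44)
  genes <- feature_fixture()
  cgis <- genomic_intervals("chr1", 12000L, 13000L)
  part <- build_partition(cgis, genes)
  cgi_pos <- seq(12010L, 12990L, by = 10L)
  prom_pos <- seq(1010L, 1990L, by = 10L)
  pos <- c(cgi_pos, prom_pos)
  p <- c(rbeta(length(cgi_pos), 20, 2), rbeta(length(prom_pos), 2, 20))
  m <- make_methylome(pos = pos, coverage = rep(60L, length(pos)),
                      meth = rbinom(length(pos), 60, p))
  prof <- region_methylation_profiles(m, part)
  expect_gte(prof$CGI.NP$quartiles[2], 80)
  expect_lte(prof$P.NCGIS$quartiles[2], 20)
})

tsg_gene <- function(id, tx_start, strand = "+") {
  g <- data.frame(gene_id = id, tx_id = id, chrom = "chr1", strand = strand,
                  tx_start = tx_start, tx_end = tx_start + 4000L,
                  cds_start = tx_start + 500L, cds_end = tx_start + 3500L,
                  stringsAsFactors = FALSE)
  g$exon_starts <- list(c(tx_start, tx_start + 2000L))
  g$exon_ends <- list(c(tx_start + 1000L, tx_start + 4000L))
  g
}

test_that("TSG overlap deduplicates genes across segments", {
  genes <- tsg_gene("tsgA", 10000L)
  # spans the promoter edge into the 5'UTR (stops before the CDS at 10500)
  dmr <- toy_dmrs_from(genomic_intervals("chr1", 9500L, 10400L))
  out <- overlap_tsg(dmr, "tsgA", genes)
  expect_setequal(out$overlaps$segment, c("promoter", "5'UTR"))
  expect_equal(unname(out$gene_counts["hyper"]), 1L)
})

test_that("non-TSG genes and unknown ids yield no overlap records", {
  genes <- tsg_gene("plainGene", 10000L)
  dmr <- toy_dmrs_from(genomic_intervals("chr1", 9500L, 10600L))
  out <- overlap_tsg(dmr, character(0), genes)
  expect_equal(nrow(out$overlaps), 0)
  expect_message(overlap_tsg(dmr, "ghost", genes), "not in the gene")
})

test_that("per-direction TSG counts follow the toy example", {
  genes <- rbind(tsg_gene("A", 10000L), tsg_gene("B", 30000L),
                 tsg_gene("C", 50000L))
  dmrs <- rbind(
    toy_dmrs_from(genomic_intervals("chr1", c(10100L, 10200L, 30100L),
                                    c(10150L, 10250L, 30150L)), "hyper"),
    toy_dmrs_from(genomic_intervals("chr1", c(30200L, 50100L),
                                    c(30250L, 50150L)), "hypo"))
  out <- overlap_tsg(dmrs, c("A", "B", "C"), genes)
  expect_equal(unname(out$gene_counts), c(2L, 2L))
})
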