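toy_annotation <- function() {
  GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(start = c(101L, 201L, 501L),
                              end = c(200L, 300L, 600L)),
    strand = c("+", "-", "+"),
    feature_id = c("gA", "gB", "gC"), type = "gene",
    seqlengths = c(chr1 = 1000L))
}

aln_df <- function(starts, lens, strands = "+") {
  data.frame(spacer_id = sprintf("s%d", seq_along(starts)),
             seq = strrep("A", lens), ref_id = "chr1", start = starts,
             strand = strands, n_mismatch = 0L, stringsAsFactors = FALSE)
}

test_that("gene assignment is strand-blind with an ambiguity policy", {
  ann <- toy_annotation()
  # inside gA; spanning gA/gB; intergenic; minus strand inside gC
  aln <- aln_df(c(150L, 195L, 350L, 550L), c(30L, 10L, 30L, 20L),
                c("+", "+", "+", "-"))
  res <- count_per_gene(aln, ann)
  expect_equal(res$counts, c(gA = 1L, gB = 0L, gC = 1L))
  expect_equal(res$summary,
               c(assigned = 2L, ambiguous = 1L, intergenic = 1L))
  # conservation: every mapped alignment lands in exactly one bucket
  expect_equal(sum(res$summary), nrow(aln))

  expect_error(count_per_gene(
    data.frame(spacer_id = "s", seq = "AAAA", ref_id = "chrX", start = 1L,
               strand = "+", stringsAsFactors = FALSE), ann),
    "absent from the annotation")
})

test_that("the low-count filter keeps exactly the >= 10 rows", {
  m <- matrix(c(4L, 5L, 5L, 5L, 0L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  f <- filter_low_counts(m)
  expect_equal(rownames(f), "b")
  expect_identical(filter_low_counts(f), f)
  expect_equal(nrow(filter_low_counts(m[0, , drop = FALSE])), 0L)
})

test_that("CPM and the VST obey their arithmetic identities", {
  m <- matrix(c(10L, 90L), nrow = 2, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(cpm(m)[, 1]), c(100000, 900000))
  big <- matrix(sample(0:50, 60, replace = TRUE), nrow = 10)
  big[1, ] <- big[1, ] + 1L
  expect_equal(unname(colSums(cpm(big))), rep(1e6, 6))
  z <- matrix(c(0L, 1000000L), nrow = 2,
              dimnames = list(c("a", "b"), "s1"))
  expect_equal(vst_counts(z)["a", 1], -1)
  expect_error(cpm(matrix(0L, 2, 1, dimnames = list(NULL, "bad"))), "bad")
})

test_that("sample ordination is deterministic and variance-ordered", {
  set.seed(101)
  m <- matrix(rnorm(200), nrow = 20,
              dimnames = list(NULL, sprintf("s%d", 1:10)))
  m <- cbind(m, s11 = m[, 1])  # duplicated sample
  p <- pca_samples(m)
  expect_equal(p$scores["s11", ], p$scores["s1", ])
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-8)
  # sign convention: rerunning gives identical scores
  expect_identical(p$scores, pca_samples(m)$scores)
  hc <- hclust_samples(m)
  expect_equal(as.integer(stats::cutree(hc, h = 1e-9)["s11"]),
               as.integer(stats::cutree(hc, h = 1e-9)["s1"]))
  expect_error(pca_samples(m[, 1, drop = FALSE]), "2 samples")
})

test_that("relative spacer count implements the stated ratio", {
  m <- matrix(c(100L, 900L), nrow = 2,
              dimnames = list(c("FbFP", "cas1"), "s1"))
  expect_equal(unname(relative_spacer_count(m, c(s1 = 5000))), 20)
  m0 <- matrix(c(0L, 1000L), nrow = 2,
               dimnames = list(c("FbFP", "cas1"), "s1"))
  expect_equal(unname(relative_spacer_count(m0, c(s1 = 5000))), 0)
  # CPM makes the ratio invariant to the count scale at fixed totals
  expect_equal(relative_spacer_count(m * 2L, c(s1 = 5000)),
               relative_spacer_count(m, c(s1 = 5000)))
  expect_error(relative_spacer_count(m, c(s2 = 1)), "s1")
  expect_error(
    relative_spacer_count(matrix(1L, 1, 1,
                                 dimnames = list("cas1", "s1")),
                          c(s1 = 1)), "FbFP")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.03, 5)), rep(0.03, 5))
  set.seed(111)
  p <- runif(50)
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("size factors follow median-of-ratios on all-positive genes", {
  set.seed(121)
  mu <- rlnorm(100, 5, 1)
  depth <- c(1, 2, 0.5, 1.5)
  counts <- sapply(depth, function(d) rpois(100, mu * d))
  rownames(counts) <- sprintf("g%d", 1:100)
  sf <- size_factors(counts)
  expect_equal(unname(sf / sf[1]), depth / depth[1], tolerance = 0.1)
  zero <- matrix(c(0L, 5L, 3L, 0L), 2)
  expect_warning(size_factors(zero), "library-size")
})

test_that("differential acquisition is symmetric and recovers planted effects", {
  sim <- simulate_count_matrix(n_genes = 300L, n_per_group = 3L, seed = 7L,
                               fold_changes = c(gene0001 = 4,
                                                gene0002 = 0.25))
  counts <- filter_low_counts(sim$counts)
  res <- diff_acquisition(counts, sim$condition)
  expect_equal(res$gene_id, rownames(counts))
  expect_true(all(res$padj >= res$pvalue - 1e-12, na.rm = TRUE))

  flipped <- diff_acquisition(counts,
                              ifelse(sim$condition == "control",
                                     "treated", "control"))
  expect_equal(flipped$log2fc, -res$log2fc, tolerance = 1e-6)
  expect_equal(flipped$pvalue, res$pvalue, tolerance = 1e-6)

  up <- res[res$gene_id == "gene0001", ]
  dn <- res[res$gene_id == "gene0002", ]
  expect_lt(up$padj, 0.05)
  expect_gt(up$log2fc, 1)
  expect_lt(dn$log2fc, -1)

  expect_error(diff_acquisition(counts, rep("control", 6)), "at least 2")
  expect_error(diff_acquisition(counts, rep("hot", 6)),
               "'control' or 'treated'")
})

test_that("fold-change estimates track an independent reference fit", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_count_matrix(n_genes = 150L, n_per_group = 4L, seed = 31L,
                               fold_changes = setNames(
                                 c(8, 4, 2, 0.5, 0.25),
                                 sprintf("gene%04d", 1:5)))
  counts <- filter_low_counts(sim$counts)
  mine <- diff_acquisition(counts, sim$condition)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      counts, S4Vectors::DataFrame(condition = sim$condition), ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- as.data.frame(DESeq2::results(dds))
  })
  m <- match(mine$gene_id, rownames(ref))
  keep <- !is.na(mine$log2fc) & !is.na(ref$log2FoldChange[m])
  expect_gt(cor(mine$log2fc[keep], ref$log2FoldChange[m][keep]), 0.95)
  # the five planted genes rank at the top by |Wald| in both analyses
  top_mine <- mine$gene_id[order(-abs(mine$wald_stat))][1:5]
  expect_setequal(top_mine, sprintf("gene%04d", 1:5))
})
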