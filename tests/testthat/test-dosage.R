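mk_expr <- function(values, chroms, batch = NULL) {
  genes <- data.frame(gene_id = rownames(values), chrom = chroms,
                      start = 1e5 * seq_len(nrow(values)),
                      end = 1e5 * seq_len(nrow(values)) + 1e4)
  expression_matrix(values, genes, batch)
}

test_that("batch centering removes additive offsets and zeroes batch means", {
  withr::with_seed(40, {
    v <- matrix(stats::rnorm(50 * 6), 50, 6,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:6)))
    batch <- stats::setNames(rep(c("FFPE", "frozen"), each = 3),
                             colnames(v))
    v_off <- v
    v_off[, batch == "FFPE"] <- v_off[, batch == "FFPE"] + 2
    m <- mk_expr(v_off, rep("chr1", 50), batch)
    centered <- batch_center(m)
    plain <- batch_center(mk_expr(v, rep("chr1", 50), batch))
    expect_equal(centered$values, plain$values)
    for (b in unique(batch)) {
      expect_true(all(abs(rowMeans(centered$values[, batch == b])) < 1e-12))
    }
    # single sample in a batch would be zeroed out: error
    bad <- stats::setNames(c("a", "b", "b", "b", "b", "b"), colnames(v))
    expect_error(batch_center(mk_expr(v, rep("chr1", 50), bad)),
                 "single sample")
  })
})

test_that("Z-scoring standardizes genes and flags flat ones", {
  v <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  colnames(v) <- c("a", "b", "c")
  z <- zscore(mk_expr(v, c("chr1", "chr1")))
  expect_equal(unname(z$values["g1", ]), c(-1, 0, 1))
  expect_equal(unname(z$values["g2", ]), c(0, 0, 0))
  expect_equal(attr(z, "zero_variance_genes"), "g2")
  withr::with_seed(41, {
    v2 <- matrix(stats::rnorm(40 * 5, sd = 3), 40, 5,
                 dimnames = list(sprintf("g%02d", 1:40), letters[1:5]))
    z2 <- zscore(mk_expr(v2, rep("chr2", 40)))
    expect_equal(unname(rowMeans(z2$values)), rep(0, 40))
    expect_equal(unname(apply(z2$values, 1, stats::sd)), rep(1, 40))
  })
  expect_error(zscore(mk_expr(v[, 1:2], c("chr1", "chr1"))), ">= 3 samples")
})

test_that("Z-scoring after batch centering ignores per-batch constants", {
  withr::with_seed(42, {
    v <- matrix(stats::rnorm(30 * 8), 30, 8,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:8)))
    batch <- stats::setNames(rep(c("x", "y"), each = 4), colnames(v))
    shifted <- v
    shifted[, batch == "y"] <- shifted[, batch == "y"] + 7.5
    a <- zscore(batch_center(mk_expr(v, rep("chr1", 30), batch)))
    b <- zscore(batch_center(mk_expr(shifted, rep("chr1", 30), batch)))
    expect_equal(a$values, b$values, tolerance = 1e-10)
  })
})

test_that("chromosome means aggregate genes by midpoint", {
  v <- rbind(g1 = c(1, 5), g2 = c(3, 7), g3 = c(10, 20))
  colnames(v) <- c("s1", "s2")
  cm <- chromosome_mean_expression(mk_expr(v, c("chr1", "chr1", "chr2")),
                                   min_genes = 1)
  expect_equal(cm["chr1", ], c(s1 = 2, s2 = 6))
  expect_equal(cm["chr2", ], c(s1 = 10, s2 = 20))
})

test_that("per-tumor CN-expression correlation is 1 for noiseless dosage", {
  truths <- lapply(1:4, function(i) {
    withr::with_seed(100 + i, simulate_karyotype(1, sim_config(), paste0("t", i)))
  })
  genome <- build_genome(sim_config())
  cfg0 <- sim_config(expr_sd = 1e-9, batch_offset = 0)
  mat <- withr::with_seed(43, simulate_expression(genome, truths, cfg0))
  cm <- chromosome_mean_expression(mat)
  for (tr in truths) {
    r <- cn_expression_correlation(truth_to_karyotype(tr), cm[, tr$tumor_id])
    expect_equal(unname(r), 1, tolerance = 1e-6)
  }
})

test_that("euploid tumors give an undefined, flagged correlation", {
  kar <- new_karyotype_for_test(rep(2L, 22), rep(FALSE, 22))
  cm <- stats::setNames(stats::rnorm(22), paste0("chr", 1:22))
  r <- cn_expression_correlation(kar, cm)
  expect_true(is.na(r))
  expect_true(attr(r, "euploid"))
})

test_that("segment mean expression orders with segment copy number", {
  genome <- build_genome(sim_config())
  truth <- structure(list(
    tumor_id = "t1",
    chromosomes = data.frame(chrom = paste0("chr", 1:22), cn = 2L,
                             loh = FALSE, stringsAsFactors = FALSE),
    segments = data.frame(chrom = "chr1", start = c(0, 1.5e6),
                          end = c(1.5e6, 3e6), cn = c(1L, 3L),
                          loh = c(TRUE, FALSE)),
    purity = 1, men1_somatic = FALSE, group = 3L
  ), class = "karyotype_truth")
  truth2 <- truth
  truth2$tumor_id <- "t2"
  truth2$segments <- NULL
  cfg0 <- sim_config(expr_sd = 0.05, batch_offset = 0, dosage_beta = 0.5)
  mat <- withr::with_seed(44, simulate_expression(genome, list(truth, truth2),
                                                  cfg0))
  segs <- data.frame(chrom = "chr1", start = c(0, 1.5e6),
                     end = c(1.5e6, 3e6), cn = c(1L, 3L))
  se <- segment_mean_expression(segs, mat, "t1")
  expect_true(all(se$n_genes >= 10))
  # loss segment below gain segment, difference ~ beta * (cn difference)
  expect_lt(se$mean_expr[1], se$mean_expr[2])
})

test_that("Mann-Whitney comparison matches the brute-force U and finds loss", {
  withr::with_seed(45, {
    x <- stats::rnorm(6)
    y <- stats::rnorm(8, 1)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    expect_equal(unname(ref$statistic), brute_U(x, y))
  })
  # constructed cohort: clear expression drop on the lost chromosome
  withr::with_seed(46, {
    n <- 12
    kars <- lapply(1:n, function(i) {
      loh <- rep(FALSE, 22)
      cn <- rep(2L, 22)
      if (i <= 6) {
        loh[11] <- TRUE
        cn[11] <- 1L
      }
      new_karyotype_for_test(cn, loh, sprintf("t%02d", i))
    })
    cm <- matrix(stats::rnorm(22 * n, 5, 0.2), 22, n,
                 dimnames = list(paste0("chr", 1:22), sprintf("t%02d", 1:n)))
    cm["chr11", 1:6] <- cm["chr11", 1:6] - 1
    res <- compare_loss_vs_intact(cm, kars, "chr11")
    expect_lt(res$p, 0.01)
    expect_equal(res$direction, "reduced")
    expect_equal(res$n_loss, 6)
    expect_error(compare_loss_vs_intact(cm[, 1:7], kars[1:7], "chr11"),
                 "both loss and intact")
  })
})
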