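toy_vcf <- system.file("extdata", "toy_somatic_synthetic.vcf",
                       package = "lohscape")
toy_bed <- system.file("extdata", "toy_blacklist_synthetic.bed",
                       package = "lohscape")

test_that("post-calling filters reject each toy variant for the right reason", {
  v <- read_variants(toy_vcf)
  expect_equal(nrow(v), 20)
  cfg <- filter_config(blacklist = read_bed(toy_bed))
  res <- filter_somatic(v, cfg)
  # hand-derived expectations, one per record
  expected <- c(
    "",                    # 60/15 vs 70/0
    "tumor_alt",           # 9 tumor ALT reads
    "normal_alt",          # 3 germline ALT reads
    "tumor_depth",         # tumor depth 45
    "normal_depth",        # normal depth 41
    "blacklist",           # inside chr2 excluded interval
    "",                    # all thresholds exactly met (50/50, 10 ALT, 2 germ)
    "tumor_depth,tumor_alt",
    "normal_alt,blacklist",
    "tumor_depth,normal_depth,tumor_alt,normal_alt,blacklist",
    "", "",
    "tumor_depth",         # tumor depth 49
    "",
    "",                    # exactly 10 tumor ALT
    "",
    "normal_alt",          # 3 germline ALT
    "tumor_alt",
    "",
    ""                     # 100 bp past the blacklist end
  )
  expect_equal(res$audited$reasons, expected)
  expect_equal(res$audited$pass, expected == "")
  expect_equal(nrow(res$pass) + nrow(res$fail), nrow(v))
  # idempotent: filtering the passing set changes nothing
  again <- filter_somatic(res$pass, cfg)
  expect_equal(nrow(again$fail), 0)
  # order-independent
  perm <- withr::with_seed(1, sample(nrow(v)))
  res_perm <- filter_somatic(v[perm, ], cfg)
  expect_equal(res_perm$audited$reasons, expected[perm])
})

test_that("malformed records are rejected with a reason, not dropped", {
  v <- data.frame(chrom = "chr1", pos = c(1, 2), t_ref = c(60, NA),
                  t_alt = c(15, 10), n_ref = 70, n_alt = 0)
  res <- filter_somatic(v, filter_config())
  expect_equal(res$audited$reasons, c("", "malformed"))
  expect_equal(nrow(res$audited), 2)
})

test_that("unopposed germline variants need LoH, ratio and a balanced germline", {
  kar <- new_karyotype_for_test(cn = c(2L, 1L, 2L),
                                loh = c(FALSE, TRUE, FALSE))
  v <- data.frame(
    chrom = c("chr2", "chr1", "chr2"), pos = c(100, 100, 200),
    gene = c("ATM_like", "other", "skewed"),
    t_ref = c(25, 50, 30), t_alt = c(70, 50, 75),
    n_ref = c(52, 50, 80), n_alt = c(48, 50, 20)
  )
  out <- unopposed_germline(v, kar, purity = 0.5)
  # chr2 locus in LoH with tumor ratio 2.8 and germline ~0.9: reported;
  # chr1 diploid balanced: not; chr2 germline BAF 0.2: not het-like
  expect_equal(out$gene, "ATM_like")
  expect_equal(out$germline_ratio, 48 / 52, tolerance = 1e-12)
  expect_equal(out$tumor_ratio, 2.8)
  expect_equal(out$expected_ratio, 2)  # 1/(1 - rho) at rho = 0.5
  # never reported on a diploid chromosome without LoH
  kar2 <- new_karyotype_for_test(cn = c(2L, 2L, 2L), loh = rep(FALSE, 3))
  expect_equal(nrow(unopposed_germline(v, kar2, purity = 0.5)), 0)
})

test_that("purity consistency of the unopposed ratio is flagged, not filtered", {
  kar <- new_karyotype_for_test(cn = 1L, loh = TRUE)
  v <- data.frame(chrom = "chr1", pos = c(10, 20), gene = c("a", "b"),
                  t_ref = c(33, 10), t_alt = c(67, 90),
                  n_ref = c(50, 50), n_alt = c(50, 50))
  out <- unopposed_germline(v, kar, purity = 0.5)
  expect_equal(nrow(out), 2)           # ratio 9 is reported too
  expect_true(out$purity_consistent[1]) # ~2.03 vs expected 2
  expect_false(out$purity_consistent[2])
})

test_that("biallelic inactivation combines variant and LoH evidence", {
  genes <- data.frame(gene_id = c("MEN1", "other"),
                      chrom = c("chr11", "chr1"),
                      start = c(1e6, 1e6), end = c(1.01e6, 1.01e6))
  kar_loh11 <- new_karyotype_for_test(
    cn = c(rep(2L, 10), 1L, rep(2L, 11)),
    loh = c(rep(FALSE, 10), TRUE, rep(FALSE, 11)))
  kar_flat <- new_karyotype_for_test(rep(2L, 22), rep(FALSE, 22))
  men1_hit <- data.frame(gene = "MEN1")
  no_hit <- data.frame(gene = character(0))
  expect_equal(biallelic_inactivation("MEN1", men1_hit, kar_loh11, genes),
               "biallelic")
  expect_equal(biallelic_inactivation("MEN1", men1_hit, kar_flat, genes),
               "monoallelic")
  expect_equal(biallelic_inactivation("MEN1", no_hit, kar_loh11, genes),
               "loh_only")
  expect_equal(biallelic_inactivation("MEN1", no_hit, kar_flat, genes),
               "wild_type")
  expect_error(biallelic_inactivation("absent", no_hit, kar_flat, genes),
               "not in annotation")
})

test_that("coding mutation rate is count per callable megabase", {
  expect_equal(coding_mutation_rate(2, 4e6), 0.5)
  expect_equal(coding_mutation_rate(0, 4e6), 0)
  expect_equal(coding_mutation_rate(5, 2.5e6), 2)
  expect_error(coding_mutation_rate(1, 0), "callable_bp")
})
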