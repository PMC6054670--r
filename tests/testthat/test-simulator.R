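test_that("genome tiling honours tile size, remainders and determinism", {
  expect_equal(nrow(tile_chromosome(3e6, 3000)), 1000)
  t2 <- tile_chromosome(3001500, 3000)
  expect_equal(nrow(t2), 1001)
  expect_equal(t2$end[1001] - t2$start[1001], 1500)
  expect_error(tile_chromosome(0, 3000), "non-positive")
  g1 <- build_genome(sim_config(seed = 9))
  g2 <- build_genome(sim_config(seed = 9))
  expect_identical(g1$snps, g2$snps)
  g3 <- build_genome(sim_config(seed = 10))
  expect_false(identical(g1$snps, g3$snps))
  # genes lie within their chromosome and the MEN1 anchor exists
  expect_true(all(g1$genes$end <= 3e6))
  expect_equal(sum(g1$genes$gene_id == "MEN1"), 1)
  expect_equal(g1$genes$chrom[g1$genes$gene_id == "MEN1"], "chr11")
})

test_that("karyotype truths encode the three stereotyped groups", {
  cfg <- sim_config()
  withr::with_seed(50, {
    t1 <- simulate_karyotype(1, cfg, "a")
    loh1 <- t1$chromosomes$chrom[t1$chromosomes$loh]
    expect_setequal(loh1, recurrent_loh_set())
    expect_gte(length(loh1), 8)
    expect_true(t1$men1_somatic)
    # configured fraction of the LoH set is copy-neutral
    cn_loh <- t1$chromosomes$cn[t1$chromosomes$loh]
    expect_equal(sum(cn_loh == 2), 2)

    t2 <- simulate_karyotype(2, cfg, "b")
    expect_equal(t2$chromosomes$chrom[t2$chromosomes$loh], "chr11")
    expect_true(t2$men1_somatic)

    cfg0 <- sim_config(group3_max_aneuploidy = 0)
    t3 <- simulate_karyotype(3, cfg0, "c")
    expect_false(t3$men1_somatic)
    expect_true(all(t3$chromosomes$cn == 2))
    expect_false(any(t3$chromosomes$loh))
    expect_true(t1$purity >= cfg$purity_range[1] &&
                  t1$purity <= cfg$purity_range[2])
  })
  expect_error(simulate_karyotype(4, cfg), "unknown group")
})

test_that("simulated coverage and BAF converge to the mixture expectations", {
  cfg <- sim_config(tile_depth = 100, snp_depth = 100,
                    n_snps_per_chrom = 200, seed = 3)
  genome <- build_genome(cfg)
  withr::with_seed(51, {
    truth <- simulate_karyotype(1, cfg, "t")
    sim <- simulate_counts(genome, truth, cfg)
  })
  rho <- truth$purity
  for (ch in c("chr1", "chr4", "chr11")) {
    st <- truth$chromosomes[truth$chromosomes$chrom == ch, ]
    expect_mix <- (rho * st$cn + 2 * (1 - rho)) / 2
    tu <- sim$tumor_tiles$count[sim$tumor_tiles$chrom == ch]
    no <- sim$normal_tiles$count[sim$normal_tiles$chrom == ch]
    r_hat <- mean(tu) / mean(no)
    # delta-method SE of the ratio of means
    se <- r_hat * sqrt(stats::var(tu) / (length(tu) * mean(tu)^2) +
                         stats::var(no) / (length(no) * mean(no)^2))
    expect_lt(abs(r_hat - expect_mix), 3 * se)
  }
  # tumor BAF at het sites on an ALT-retained monosomic chromosome
  st <- sim$snp_truth
  sel <- st$genotype == "het" & st$loh & st$cn == 1 & st$alt_copies == 1
  baf <- sim$tumor_alleles$alt_count[sel] /
    (sim$tumor_alleles$alt_count[sel] + sim$tumor_alleles$ref_count[sel])
  expected <- expected_baf(rho, 1, 1)
  se <- stats::sd(baf) / sqrt(length(baf))
  expect_lt(abs(mean(baf) - expected), 3 * se)
})

test_that("a pure-tumor monosomy halves mean tile coverage", {
  cfg <- sim_config(purity_range = c(1, 1), tile_depth = 200, seed = 4)
  genome <- build_genome(cfg)
  withr::with_seed(52, {
    truth <- simulate_karyotype(2, cfg, "t")  # chr11 monosomy, rho = 1
    sim <- simulate_counts(genome, truth, cfg)
  })
  m11 <- mean(sim$tumor_tiles$count[sim$tumor_tiles$chrom == "chr11"])
  mnorm <- mean(sim$normal_tiles$count[sim$normal_tiles$chrom == "chr11"])
  expect_equal(m11 / mnorm, 0.5, tolerance = 0.02)
})

test_that("injected variants carry the designed allele ratios and artifacts", {
  cfg <- sim_config(purity_range = c(0.5, 0.5), snp_depth = 4000, seed = 5)
  genome <- build_genome(cfg)
  bl <- data.frame(chrom = "chr3", start = 1.5e6, end = 1.506e6)
  withr::with_seed(53, {
    truth <- simulate_karyotype(2, cfg, "t")
    v <- simulate_variants(genome, truth, cfg, blacklist = bl)
  })
  # unopposed germline variant on the LoH chromosome: ALT:REF -> 1/(1-rho)=2
  unop <- v$germline[v$germline$truth_class == "unopposed", ]
  expect_equal(nrow(unop), 1)  # group 2: only chr11 has LoH
  ratio <- unop$t_alt / unop$t_ref
  expect_equal(ratio, 2, tolerance = 0.15)
  opp <- v$germline[v$germline$truth_class == "opposed", ]
  expect_equal(opp$t_alt / opp$t_ref, rep(1, nrow(opp)), tolerance = 0.15)
  # artifact designed to fail the germline-support filter carries 3 ALT reads
  art <- v$somatic[v$somatic$truth_class == "artifact_germline_support", ]
  expect_equal(art$n_alt, 3)
  expect_true("artifact_blacklist" %in% v$somatic$truth_class)
  # MEN1 driver sits on chr11 with VAF near rho/(2-rho)
  men1 <- v$somatic[v$somatic$truth_class == "driver", ]
  expect_equal(men1$chrom, "chr11")
  expect_equal(men1$t_alt / (men1$t_alt + men1$t_ref), 0.5 / 1.5,
               tolerance = 0.1)
})

test_that("the full cohort simulation is reproducible from its seed", {
  cfg <- sim_config(n_tumors = c(group1 = 1, group2 = 1, group3 = 1),
                    seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$tumors, b$tumors)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(lapply(a$truths, `[[`, "purity"),
                   lapply(b$truths, `[[`, "purity"))
  c2 <- simulate_cohort(sim_config(n_tumors = c(group1 = 1, group2 = 1,
                                                group3 = 1), seed = 78))
  expect_false(identical(a$tumors, c2$tumors))
})

test_that("truth karyotypes round-trip through group classification", {
  co <- small_cohort()
  kars <- lapply(co$truths, truth_to_karyotype)
  men1 <- vapply(co$truths, `[[`, logical(1), "men1_somatic")
  rec <- mine_recurrent_loh(kars)
  expect_setequal(rec$chromosomes, recurrent_loh_set())
  g <- classify_groups(kars, men1, rec)
  truth_groups <- vapply(co$truths, `[[`, integer(1), "group")
  expect_equal(g$group, unname(truth_groups[g$tumor_id]))
})

test_that("cohort files round-trip through the on-disk formats", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, file.path(dir, "cohort"))
  expect_error(write_cohort(co, file.path(dir, "cohort")), "refusing")
  back <- load_cohort(file.path(dir, "cohort"))
  expect_equal(names(back$tumors), names(co$tumors))
  expect_equal(back$tumors[[1]]$normal_tiles$count,
               co$tumors[[1]]$normal_tiles$count)
  expect_equal(back$tumors[[3]]$tumor_alleles$alt_count,
               co$tumors[[3]]$tumor_alleles$alt_count)
  expect_equal(back$truths[[1]]$chromosomes$cn,
               co$truths[[1]]$chromosomes$cn)
  expect_equal(back$truths[[5]]$purity, co$truths[[5]]$purity,
               tolerance = 1e-12)
  expect_equal(dim(back$expression$values), dim(co$expression$values))
  expect_equal(unname(back$expression$values[3, 2]),
               unname(co$expression$values[3, 2]), tolerance = 1e-6)
  expect_equal(back$clinical$metastasis, co$clinical$metastasis)
  v <- back$tumors[[1]]$somatic
  expect_true(all(c("t_ref", "t_alt", "n_ref", "n_alt") %in% names(v)))
})
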