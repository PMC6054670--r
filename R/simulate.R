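# Synthetic tumor/normal cohort generator with known ground truth.
#
# The generator emulates the observable summaries the inference stages
# consume -- tile read counts, SNP allele counts, variant tables, a log2
# expression matrix, clinical labels -- under integer chromosome/segment copy
# number, stromal admixture, and three stereotyped karyotype groups:
#   Group 1: somatic MEN1 mutation + LoH of a recurrent 10-chromosome set
#            (a configurable fraction copy-neutral);
#   Group 2: somatic MEN1 mutation + chromosome 11 LoH only;
#   Group 3: no MEN1 mutation, random aneuploidy from euploid to extensive.

#' Canonical recurrent-LoH chromosome set used by the Group 1 simulation
#' @return Character vector of chromosome names.
#' @export
recurrent_loh_set <- function() {
  paste0("chr", c(1, 2, 3, 6, 8, 10, 11, 16, 21, 22))
}

#' Simulate one tumor's karyotype truth
#'
#' Draws from the current RNG stream (seed management belongs to the caller;
#' [simulate_cohort()] derives a fixed stream from \code{config$seed}).
#'
#' @param group Karyotype group, 1, 2 or 3.
#' @param config A [sim_config()].
#' @param tumor_id Identifier stored in the truth record.
#' @return List of class \code{karyotype_truth}: \code{tumor_id},
#'   \code{chromosomes} (data.frame chrom, cn, loh), \code{segments}
#'   (optional data.frame chrom, start, end, cn, loh of overrides, or NULL),
#'   \code{purity}, \code{men1_somatic}, \code{group}.
#' @export
simulate_karyotype <- function(group, config = sim_config(),
                               tumor_id = NA_character_) {
  if (!group %in% 1:3) stop("unknown group: ", group)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  cn <- rep(2L, length(chroms))
  loh <- rep(FALSE, length(chroms))
  names(cn) <- names(loh) <- chroms
  men1 <- FALSE
  if (group == 1) {
    set <- intersect(recurrent_loh_set(), chroms)
    loh[set] <- TRUE
    cn[set] <- 1L
    n_cnloh <- round(config$cnloh_fraction * length(set))
    if (n_cnloh > 0) {
      cnloh <- sample(setdiff(set, "chr11"), n_cnloh)
      cn[cnloh] <- 2L  # copy-neutral LoH
    }
    men1 <- TRUE
  } else if (group == 2) {
    loh["chr11"] <- TRUE
    cn["chr11"] <- 1L
    men1 <- TRUE
  } else {
    n_ab <- sample.int(config$group3_max_aneuploidy + 1L, 1L) - 1L
    if (n_ab > 0) {
      ab <- sample(chroms, n_ab)
      for (ch in ab) {
        if (stats::runif(1) < 0.6) {
          cn[ch] <- 1L
          loh[ch] <- TRUE
        } else {
          cn[ch] <- 3L
        }
      }
    }
  }
  purity <- stats::runif(1, config$purity_range[1], config$purity_range[2])
  structure(list(
    tumor_id = tumor_id,
    chromosomes = data.frame(chrom = chroms, cn = unname(cn),
                             loh = unname(loh), stringsAsFactors = FALSE),
    segments = NULL,
    purity = purity,
    men1_somatic = men1,
    group = as.integer(group)
  ), class = "karyotype_truth")
}

# Truth lookup: copy number and LoH state at arbitrary positions, honouring
# segmental overrides where present.
truth_state_at <- function(truth, chrom, pos) {
  idx <- match(chrom, truth$chromosomes$chrom)
  if (anyNA(idx)) stop("position on chromosome absent from truth")
  cn <- truth$chromosomes$cn[idx]
  loh <- truth$chromosomes$loh[idx]
  seg <- truth$segments
  if (!is.null(seg) && nrow(seg)) {
    for (k in seq_len(nrow(seg))) {
      hit <- chrom == seg$chrom[k] & pos >= seg$start[k] & pos < seg$end[k]
      cn[hit] <- seg$cn[k]
      loh[hit] <- seg$loh[k]
    }
  }
  list(cn = cn, loh = loh)
}

rbetabinom <- function(n, size, prob, precision) {
  p <- numeric(n)
  inner <- prob > 0 & prob < 1
  p[inner] <- stats::rbeta(sum(inner), prob[inner] * precision,
                           (1 - prob[inner]) * precision)
  p[!inner] <- prob[!inner]
  stats::rbinom(n, size, p)
}

#' Simulate tile read-count tracks and SNP allele counts for one tumor
#'
#' Normal tile counts are negative-binomial around the configured depth;
#' tumor tile counts have mean \code{depth * (rho*c + 2(1-rho))/2} from the
#' purity mixture. Germline SNPs are heterozygous (ALT fraction 1/2) or
#' homozygous; tumor ALT counts at het sites follow the beta-binomial around
#' [expected_baf()] given the local truth CN/LoH and a randomly retained
#' haplotype. Site depths are Poisson around the configured SNP depth.
#'
#' @param genome A [build_genome()] scaffold.
#' @param truth A [simulate_karyotype()] truth.
#' @param config A [sim_config()].
#' @return List with \code{normal_tiles}, \code{tumor_tiles} (data.frames
#'   chrom, start, end, count), \code{normal_alleles}, \code{tumor_alleles}
#'   (\code{allele_counts} tables) and \code{snp_truth} (per-site genotype,
#'   CN, LoH, ALT copy number in tumor).
#' @export
simulate_counts <- function(genome, truth, config = sim_config()) {
  stopifnot(all(truth$chromosomes$chrom %in% genome$chromosomes$chrom))
  tiles <- genome$tiles
  mid <- (tiles$start + tiles$end) / 2
  st <- truth_state_at(truth, tiles$chrom, mid)
  rho <- truth$purity
  mix <- (rho * st$cn + 2 * (1 - rho)) / 2
  frac <- (tiles$end - tiles$start) / genome$tile_size  # short last tiles
  n_tiles <- nrow(tiles)
  normal_ct <- stats::rnbinom(n_tiles, size = config$tile_nb_size,
                              mu = config$tile_depth * frac)
  tumor_ct <- stats::rnbinom(n_tiles, size = config$tile_nb_size,
                             mu = config$tile_depth * frac * mix)
  normal_tiles <- cbind(tiles, count = normal_ct)
  tumor_tiles <- cbind(tiles, count = tumor_ct)

  snps <- genome$snps
  n_snp <- nrow(snps)
  gt <- sample(c("het", "hom_ref", "hom_alt"), n_snp, replace = TRUE,
               prob = c(config$het_fraction,
                        (1 - config$het_fraction) * 0.7,
                        (1 - config$het_fraction) * 0.3))
  g_frac <- c(het = 0.5, hom_ref = 0.01, hom_alt = 0.99)[gt]
  n_depth <- stats::rpois(n_snp, config$snp_depth)
  n_depth <- pmax(n_depth, 1L)
  n_alt <- rbetabinom(n_snp, n_depth, g_frac, config$baf_precision)

  sst <- truth_state_at(truth, snps$chrom, snps$pos)
  alt_retained <- stats::runif(n_snp) < 0.5
  a <- integer(n_snp)
  is_het <- gt == "het"
  # het sites: ALT copies in tumor cells given CN/LoH and retained haplotype
  a[is_het & sst$loh] <- ifelse(alt_retained[is_het & sst$loh],
                                sst$cn[is_het & sst$loh], 0L)
  bal <- is_het & !sst$loh
  a[bal] <- ifelse(sst$cn[bal] == 2, 1L,
                   ifelse(alt_retained[bal], pmax(sst$cn[bal] - 1L, 0L),
                          pmin(1L, sst$cn[bal])))
  a[gt == "hom_alt"] <- sst$cn[gt == "hom_alt"]
  t_frac <- numeric(n_snp)
  ok <- !(rho == 1 & sst$cn == 0)
  t_frac[ok] <- expected_baf(rho, sst$cn[ok], a[ok])
  t_frac[!ok] <- 0.5
  # homozygous sites keep a small error-rate floor/ceiling in the tumor too
  t_frac[gt == "hom_ref"] <- 0.01
  t_frac[gt == "hom_alt"] <- 0.99
  t_depth <- pmax(stats::rpois(n_snp, config$snp_depth * mix_at(
    rho, sst$cn)), 1L)
  t_alt <- rbetabinom(n_snp, t_depth, t_frac, config$baf_precision)

  list(
    normal_tiles = normal_tiles,
    tumor_tiles = tumor_tiles,
    normal_alleles = allele_counts(snps$chrom, snps$pos,
                                   ref_count = n_depth - n_alt,
                                   alt_count = n_alt,
                                   sample_id = paste0(truth$tumor_id, "_N")),
    tumor_alleles = allele_counts(snps$chrom, snps$pos,
                                  ref_count = t_depth - t_alt,
                                  alt_count = t_alt,
                                  sample_id = paste0(truth$tumor_id, "_T")),
    snp_truth = data.frame(chrom = snps$chrom, pos = snps$pos, genotype = gt,
                           cn = sst$cn, loh = sst$loh, alt_copies = a,
                           stringsAsFactors = FALSE)
  )
}

mix_at <- function(rho, cn) (rho * cn + 2 * (1 - rho)) / 2

#' Simulate somatic and germline variant tables for one tumor
#'
#' Injects a somatic MEN1 variant (for MEN1-mutant truths) with read counts
#' consistent with the retained-allele frequency under the local CN/LoH
#' state; germline heterozygous variants, some on LoH chromosomes (hence
#' unopposed in the tumor, ALT retained) and some on diploid chromosomes;
#' and below-threshold artifacts (low depth, low tumor support,
#' germline-supported, blacklisted) that downstream filters must reject.
#'
#' @inheritParams simulate_counts
#' @param blacklist Optional data.frame (chrom, start, end; 0-based
#'   half-open) of excluded regions; one artifact is placed inside the first
#'   interval when provided.
#' @return List with \code{somatic} and \code{germline} variant data.frames
#'   (columns chrom, pos, ref, alt, gene, effect, t_ref, t_alt, n_ref, n_alt,
#'   origin, truth_class).
#' @export
simulate_variants <- function(genome, truth, config = sim_config(),
                              blacklist = NULL) {
  rho <- truth$purity
  depth <- config$snp_depth
  genes <- genome$genes
  gene_mid <- function(g) as.integer((g$start + g$end) / 2)

  mk <- function(chrom, pos, gene, effect, t_frac, n_frac, origin,
                 truth_class, t_depth = depth, n_depth = depth) {
    td <- max(1L, stats::rpois(1, t_depth))
    nd <- max(1L, stats::rpois(1, n_depth))
    ta <- stats::rbinom(1, td, t_frac)
    na <- stats::rbinom(1, nd, n_frac)
    data.frame(chrom = chrom, pos = as.integer(pos), ref = "C", alt = "T",
               gene = gene, effect = effect,
               t_ref = td - ta, t_alt = ta, n_ref = nd - na, n_alt = na,
               origin = origin, truth_class = truth_class,
               stringsAsFactors = FALSE)
  }

  somatic <- list()
  if (truth$men1_somatic) {
    men1 <- genes[genes$gene_id == "MEN1", ]
    if (!nrow(men1)) stop("MEN1 gene absent from genome model")
    pos <- gene_mid(men1)
    st <- truth_state_at(truth, men1$chrom, pos)
    a_mut <- if (st$loh) st$cn else 1L  # mutation on the retained allele
    vaf <- if (rho == 1 && st$cn == 0) 0 else
      rho * a_mut / (rho * st$cn + 2 * (1 - rho))
    somatic$men1 <- mk(men1$chrom, pos, "MEN1",
                       sample(c("nonsense", "frameshift", "missense"), 1),
                       vaf, 0.001, "somatic", "driver")
  }
  # passenger somatic variants on random genes
  n_pass <- 2L
  pass_genes <- genes[sample.int(nrow(genes), n_pass), ]
  for (i in seq_len(n_pass)) {
    g <- pass_genes[i, ]
    pos <- gene_mid(g)
    st <- truth_state_at(truth, g$chrom, pos)
    vaf <- if (rho == 1 && st$cn == 0) 0 else
      rho * 1 / (rho * st$cn + 2 * (1 - rho))
    somatic[[paste0("pass", i)]] <-
      mk(g$chrom, pos, g$gene_id, "missense", vaf, 0.001, "somatic",
         "passenger")
  }
  # artifacts that must fail the post-calling filters
  art_genes <- genes[sample.int(nrow(genes), 4L), ]
  somatic$art_depth <- mk(art_genes$chrom[1], gene_mid(art_genes[1, ]) + 7L,
                          art_genes$gene_id[1], "missense", 0.4, 0.001,
                          "somatic", "artifact_low_depth",
                          t_depth = 25, n_depth = 25)
  somatic$art_alt <- within(
    mk(art_genes$chrom[2], gene_mid(art_genes[2, ]) + 7L,
       art_genes$gene_id[2], "missense", 0.0, 0.001, "somatic",
       "artifact_low_alt"),
    {
      t_alt <- 5L
      t_ref <- t_ref - 5L
    })
  somatic$art_germ <- within(
    mk(art_genes$chrom[3], gene_mid(art_genes[3, ]) + 7L,
       art_genes$gene_id[3], "missense", 0.35, 0.0, "somatic",
       "artifact_germline_support"),
    {
      n_alt <- 3L
      n_ref <- n_ref - 3L
    })
  if (!is.null(blacklist) && nrow(blacklist)) {
    bpos <- as.integer((blacklist$start[1] + blacklist$end[1]) / 2) + 1L
    somatic$art_bl <- mk(blacklist$chrom[1], bpos, "intergenic", "other",
                         0.4, 0.001, "somatic", "artifact_blacklist")
  }

  # germline het variants: two on LoH chromosomes (ALT retained -> unopposed
  # in the tumor), two on balanced diploid chromosomes
  loh_ch <- truth$chromosomes$chrom[truth$chromosomes$loh]
  dip_ch <- truth$chromosomes$chrom[!truth$chromosomes$loh &
                                      truth$chromosomes$cn == 2]
  germline <- list()
  pick_gene <- function(ch) {
    gs <- genes[genes$chrom == ch, ]
    gs[sample.int(nrow(gs), 1L), ]
  }
  for (ch in utils::head(loh_ch, 2)) {
    g <- pick_gene(ch)
    pos <- gene_mid(g) + 11L
    st <- truth_state_at(truth, g$chrom, pos)
    b <- if (st$cn == 0 && rho == 1) 0.5 else expected_baf(rho, st$cn, st$cn)
    germline[[paste0("unop_", ch)]] <-
      mk(g$chrom, pos, g$gene_id, "missense", b, 0.5, "germline", "unopposed")
  }
  for (ch in utils::head(dip_ch, 2)) {
    g <- pick_gene(ch)
    germline[[paste0("opp_", ch)]] <-
      mk(g$chrom, gene_mid(g) + 11L, g$gene_id, "missense", 0.5, 0.5,
         "germline", "opposed")
  }
  list(somatic = do.call(rbind, unname(somatic)),
       germline = do.call(rbind, unname(germline)))
}

#' Simulate a cohort expression matrix with a chromosome dosage effect
#'
#' log2 expression of gene g in tumor t is
#' \code{baseline_g + beta * (cn - 2) + batch_offset + N(0, sd)}, with the
#' local copy number taken at the gene midpoint and two batches assigned
#' alternately (emulating an archival-vs-frozen preservation split).
#'
#' @param genome A [build_genome()] scaffold.
#' @param truths List of [simulate_karyotype()] truths (>= 2).
#' @param config A [sim_config()].
#' @return List of class \code{expression_matrix}: \code{values} (gene x
#'   sample matrix), \code{genes} (coordinates), \code{batch} (named vector).
#' @export
simulate_expression <- function(genome, truths, config = sim_config()) {
  if (length(truths) < 2) stop("need >= 2 tumors for an expression matrix")
  genes <- genome$genes
  ids <- vapply(truths, `[[`, character(1), "tumor_id")
  baseline <- stats::rnorm(nrow(genes), mean = 6, sd = 1)
  # center baselines within each chromosome: between-gene variation stays,
  # but chromosome-scale expression differences are purely dosage-driven
  baseline <- baseline - stats::ave(baseline, genes$chrom) + 6
  mid <- as.integer((genes$start + genes$end) / 2)
  vals <- sapply(truths, function(tr) {
    st <- truth_state_at(tr, genes$chrom, mid)
    baseline + config$dosage_beta * (st$cn - 2) +
      stats::rnorm(nrow(genes), sd = config$expr_sd)
  })
  colnames(vals) <- ids
  rownames(vals) <- genes$gene_id
  batch <- rep(c("FFPE", "frozen"), length.out = length(ids))
  names(batch) <- ids
  vals <- vals + rep(ifelse(batch == "FFPE", config$batch_offset, 0),
                     each = nrow(genes))
  structure(list(values = vals, genes = genes, batch = batch),
            class = "expression_matrix")
}

#' Simulate clinical annotations with group-linked severity
#'
#' Metastasis probability and grade distribution differ by karyotype group
#' (Group 1 most severe, Group 2 indolent), so that the exact-test
#' association machinery has signal to find.
#'
#' @param truths List of karyotype truths.
#' @return data.frame with tumor_id, group, grade, metastasis.
#' @export
simulate_clinical <- function(truths) {
  ids <- vapply(truths, `[[`, character(1), "tumor_id")
  grp <- vapply(truths, `[[`, integer(1), "group")
  met_p <- c(0.4, 0.02, 0.15)[grp]
  grade <- character(length(grp))
  for (i in seq_along(grp)) {
    grade[i] <- switch(grp[i],
      sample(c("G2", "G3"), 1, prob = c(0.6, 0.4)),
      sample(c("G1", "G2"), 1, prob = c(0.9, 0.1)),
      sample(c("G1", "G2", "G3"), 1, prob = c(0.5, 0.35, 0.15)))
  }
  data.frame(tumor_id = ids, group = grp, grade = grade,
             metastasis = stats::runif(length(grp)) < met_p,
             stringsAsFactors = FALSE)
}

#' Simulate a complete tumor/normal cohort with ground truth
#'
#' Deterministic given \code{config$seed}: builds the genome scaffold, draws
#' per-group karyotype truths, per-tumor count tracks, allele tables and
#' variant tables, a cohort expression matrix, clinical labels and a small
#' mappability blacklist.
#'
#' @param config A [sim_config()].
#' @return List of class \code{sim_cohort}: \code{genome}, \code{truths},
#'   \code{tumors} (per-tumor list of counts and variants), \code{expression},
#'   \code{clinical}, \code{blacklist}, \code{config}.
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  genome <- build_genome(config)
  rng <- local_rng(config$seed, "cohort")
  groups <- rep(1:3, times = c(config$n_tumors[["group1"]],
                               config$n_tumors[["group2"]],
                               config$n_tumors[["group3"]]))
  ids <- sprintf("T%02d", seq_along(groups))
  blk_ch <- genome$chromosomes$chrom[
    seq(1, nrow(genome$chromosomes), length.out = min(3, nrow(genome$chromosomes)))]
  blacklist <- data.frame(
    chrom = blk_ch,
    start = as.integer(0.55 * config$chrom_length),
    end = as.integer(0.55 * config$chrom_length) + 2L * config$tile_size,
    stringsAsFactors = FALSE
  )
  truths <- vector("list", length(groups))
  tumors <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    truths[[i]] <- with_rng(rng, simulate_karyotype(groups[i], config, ids[i]))
    cnt <- with_rng(rng, simulate_counts(genome, truths[[i]], config))
    var <- with_rng(rng, simulate_variants(genome, truths[[i]], config,
                                           blacklist))
    tumors[[i]] <- c(cnt, var)
  }
  names(truths) <- names(tumors) <- ids
  expression <- with_rng(rng, simulate_expression(genome, truths, config))
  clinical <- with_rng(rng, simulate_clinical(truths))
  structure(list(genome = genome, truths = truths, tumors = tumors,
                 expression = expression, clinical = clinical,
                 blacklist = blacklist, config = config),
            class = "sim_cohort")
}

#' Convert a karyotype truth into the karyotype call structure
#'
#' Used by round-trip tests and truth-vs-called comparisons: the noiseless
#' limit of the inference.
#'
#' @param truth A \code{karyotype_truth}.
#' @return A \code{karyotype} object as produced by [build_karyotype()].
#' @export
truth_to_karyotype <- function(truth) {
  calls <- data.frame(
    chrom = truth$chromosomes$chrom,
    dominant_cn = truth$chromosomes$cn,
    loh = truth$chromosomes$loh,
    support_fraction = 1,
    heterogeneous = FALSE,
    stringsAsFactors = FALSE
  )
  new_karyotype(truth$tumor_id, calls)
}
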