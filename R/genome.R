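# Coordinate scaffold shared by every stage: chromosomes, tiles, SNP
# positions and gene models. Desk-scale by default (22 autosomes of 3 Mb);
# real hg19-scale tracks load into the same structures since all coordinates
# are genome-model-relative.

#' Simulation / genome configuration
#'
#' Bundles every tunable of the synthetic-cohort generator, with defaults
#' describing a desk-scale study: 22 autosomes of 3 Mb tiled at 3 kb, 200 SNP
#' positions and 50 genes per chromosome, mean tile and SNP depth 150x,
#' negative-binomial tile noise, beta-binomial allele noise, tumor purity
#' uniform on 0.4--0.8, and an expression dosage slope of 0.5 log2 units per
#' copy with 0.3 SD residual noise.
#'
#' @param n_tumors Named integer vector: tumors per karyotype group.
#' @param n_chromosomes Number of autosomes.
#' @param chrom_length Chromosome length in bp.
#' @param tile_size Tile width in bp (3000 mirrors 3 kb genome tiles).
#' @param n_snps_per_chrom Germline SNP positions per chromosome.
#' @param n_genes_per_chrom Genes per chromosome.
#' @param tile_depth Mean normal-sample read count per tile.
#' @param snp_depth Mean site depth at SNP positions.
#' @param tile_nb_size Negative-binomial size (dispersion) for tile counts;
#'   larger is closer to Poisson.
#' @param baf_precision Beta-binomial precision for allele counts; larger is
#'   closer to binomial.
#' @param het_fraction Fraction of SNP positions that are germline
#'   heterozygous (the rest are homozygous REF or ALT).
#' @param purity_range Tumor purity sampled uniformly from this interval.
#' @param cnloh_fraction Fraction of Group 1 LoH chromosomes rendered
#'   copy-neutral (CN 2 with LoH) instead of monosomic.
#' @param group3_max_aneuploidy Maximum number of aberrant chromosomes in a
#'   Group 3 tumor (actual number uniform on 0..max).
#' @param dosage_beta Expression dosage slope, log2 units per copy deviation
#'   from diploid.
#' @param expr_sd Residual SD of log2 expression.
#' @param batch_offset Additive offset of the second expression batch,
#'   emulating a fixed-vs-frozen preservation split.
#' @param seed Integer seed; fixing it makes every simulator output
#'   reproducible.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_tumors = c(group1 = 10, group2 = 16, group3 = 13),
                       n_chromosomes = 22,
                       chrom_length = 3e6,
                       tile_size = 3000,
                       n_snps_per_chrom = 200,
                       n_genes_per_chrom = 50,
                       tile_depth = 150,
                       snp_depth = 150,
                       tile_nb_size = 50,
                       baf_precision = 200,
                       het_fraction = 0.6,
                       purity_range = c(0.4, 0.8),
                       cnloh_fraction = 0.2,
                       group3_max_aneuploidy = 6,
                       dosage_beta = 0.5,
                       expr_sd = 0.3,
                       batch_offset = 1.0,
                       seed = 1L) {
  cfg <- list(
    n_tumors = n_tumors, n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length), tile_size = as.integer(tile_size),
    n_snps_per_chrom = as.integer(n_snps_per_chrom),
    n_genes_per_chrom = as.integer(n_genes_per_chrom),
    tile_depth = tile_depth, snp_depth = snp_depth,
    tile_nb_size = tile_nb_size, baf_precision = baf_precision,
    het_fraction = het_fraction, purity_range = purity_range,
    cnloh_fraction = cnloh_fraction,
    group3_max_aneuploidy = as.integer(group3_max_aneuploidy),
    dosage_beta = dosage_beta, expr_sd = expr_sd,
    batch_offset = batch_offset, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  pos <- c("n_chromosomes", "chrom_length", "tile_size", "n_snps_per_chrom",
           "n_genes_per_chrom", "tile_depth", "snp_depth", "tile_nb_size",
           "baf_precision")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      stop("sim_config: '", f, "' must be a positive scalar")
    }
  }
  pr <- cfg$purity_range
  if (length(pr) != 2 || pr[1] <= 0 || pr[2] > 1 || pr[1] > pr[2]) {
    stop("sim_config: purity_range must lie within (0, 1]")
  }
  if (cfg$het_fraction <= 0 || cfg$het_fraction > 1) {
    stop("sim_config: het_fraction must be in (0, 1]")
  }
  if (any(cfg$n_tumors < 0)) stop("sim_config: negative n_tumors")
  invisible(cfg)
}

#' Tile a chromosome into half-open windows
#'
#' @param length_bp Chromosome length.
#' @param tile_size Tile width; the last tile may be shorter.
#' @return data.frame with 0-based half-open \code{start}, \code{end}.
#' @export
tile_chromosome <- function(length_bp, tile_size) {
  if (length_bp <= 0 || tile_size <= 0) stop("non-positive size")
  starts <- seq(0L, length_bp - 1L, by = tile_size)
  data.frame(start = starts, end = pmin(starts + tile_size, length_bp))
}

#' Build the coordinate scaffold
#'
#' Deterministic given \code{config$seed}: chromosomes chr1..chrN of equal
#' length, 3 kb-style tiling, sorted SNP positions sampled uniformly without
#' replacement, and non-overlapping gene intervals laid out evenly. One gene
#' on chr11 is labelled \code{MEN1} so that tumor-suppressor bookkeeping
#' (biallelic inactivation, group classification) has a concrete anchor.
#'
#' @param config A [sim_config()].
#' @return List of class \code{genome_model} with elements
#'   \code{chromosomes} (name, length), \code{tile_size}, \code{tiles}
#'   (chrom, start, end), \code{snps} (chrom, pos 1-based), \code{genes}
#'   (gene_id, chrom, start, end, 1-based inclusive).
#' @export
build_genome <- function(config = sim_config()) {
  validate_sim_config(config)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  chrom_df <- data.frame(chrom = chroms, length = config$chrom_length,
                         stringsAsFactors = FALSE)
  tiles <- do.call(rbind, lapply(chroms, function(ch) {
    t <- tile_chromosome(config$chrom_length, config$tile_size)
    cbind(data.frame(chrom = ch, stringsAsFactors = FALSE), t)
  }))
  rng <- local_rng(config$seed, "genome")
  snps <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- sort(sample_int(rng, config$chrom_length, config$n_snps_per_chrom))
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  gene_span <- floor(config$chrom_length / config$n_genes_per_chrom)
  glen <- max(1L, floor(gene_span * 0.5))
  genes <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    start <- (seq_len(config$n_genes_per_chrom) - 1L) * gene_span + 1L
    data.frame(
      gene_id = sprintf("g%02d_%03d", i, seq_len(config$n_genes_per_chrom)),
      chrom = chroms[i], start = start, end = start + glen - 1L,
      stringsAsFactors = FALSE
    )
  }))
  if ("chr11" %in% chroms) {
    mid <- which(genes$chrom == "chr11")
    genes$gene_id[mid[ceiling(length(mid) / 2)]] <- "MEN1"
  }
  structure(list(chromosomes = chrom_df, tile_size = config$tile_size,
                 tiles = tiles, snps = snps, genes = genes),
            class = "genome_model")
}

# Derive an independent RNG stream from the master seed and a stage tag, so
# stages can be re-run independently yet reproducibly. Streams never touch
# .Random.seed of the caller.
local_rng <- function(seed, tag) {
  sub <- (as.numeric(seed) * 1009 + sum(utf8ToInt(tag))) %% 2147483629
  env <- new.env()
  env$seed <- as.integer(sub)
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(rng$seed)
  res <- expr
  rng$seed <- as.integer((as.numeric(rng$seed) * 69069 + 1) %% 2147483629)
  res
}

sample_int <- function(rng, n, k) {
  with_rng(rng, sample.int(n, k))
}
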