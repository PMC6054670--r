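# Cohort-level input/output: simulator exports and their re-import.

#' Write a simulated cohort to disk in standard text formats
#'
#' Per tumor: \code{<id>.normal.tiles.tsv} / \code{<id>.tumor.tiles.tsv}
#' (BED-style 0-based half-open, chrom/start/end/count),
#' \code{<id>.normal.alleles.tsv} / \code{<id>.tumor.alleles.tsv}, and
#' \code{<id>.variants.vcf} (minimal VCF, TUMOR/NORMAL AD fields). Cohort
#' level: \code{expression.tsv} (genes x samples with coordinate columns),
#' \code{clinical.tsv}, \code{blacklist.bed}, \code{truth.json},
#' \code{config.yaml}.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created; refuses to overwrite an existing
#'   truth.json).
#' @return Invisibly, \code{dir}.
#' @export
write_cohort <- function(cohort, dir) {
  if (file.exists(file.path(dir, "truth.json"))) {
    stop("refusing to overwrite existing cohort in ", dir)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (id in names(cohort$tumors)) {
    tu <- cohort$tumors[[id]]
    wt(tu$normal_tiles, paste0(id, ".normal.tiles.tsv"))
    wt(tu$tumor_tiles, paste0(id, ".tumor.tiles.tsv"))
    wt(as.data.frame(tu$normal_alleles), paste0(id, ".normal.alleles.tsv"))
    wt(as.data.frame(tu$tumor_alleles), paste0(id, ".tumor.alleles.tsv"))
    write_variants_vcf(rbind(tu$somatic, tu$germline),
                       file.path(dir, paste0(id, ".variants.vcf")))
  }
  expr <- cohort$expression
  expr_df <- cbind(expr$genes[, c("gene_id", "chrom", "start", "end")],
                   as.data.frame(expr$values))
  wt(expr_df, "expression.tsv")
  writeLines(paste0("# batch labels: ",
                    paste(names(expr$batch), expr$batch, sep = "=",
                          collapse = ",")),
             file.path(dir, "batches.txt"))
  wt(cohort$clinical, "clinical.tsv")
  utils::write.table(cohort$blacklist, file.path(dir, "blacklist.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  truth_out <- lapply(cohort$truths, function(tr) {
    list(tumor_id = tr$tumor_id, purity = tr$purity,
         men1_somatic = tr$men1_somatic, group = tr$group,
         chromosomes = tr$chromosomes, segments = tr$segments)
  })
  jsonlite::write_json(truth_out, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg <- cohort$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Load a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A list shaped like a [simulate_cohort()] result (genome rebuilt
#'   from config.yaml; truths restored from truth.json when present).
#' @export
load_cohort <- function(dir) {
  cfg_l <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- do.call(sim_config, cfg_l[setdiff(names(cfg_l), character(0))])
  genome <- build_genome(cfg)
  truth_path <- file.path(dir, "truth.json")
  truths <- NULL
  if (file.exists(truth_path)) {
    raw <- jsonlite::read_json(truth_path, simplifyVector = TRUE,
                               simplifyDataFrame = TRUE)
    truths <- lapply(raw, function(tr) {
      segs <- tr$segments
      if (!is.null(segs) && !is.data.frame(segs)) segs <- NULL
      structure(list(tumor_id = tr$tumor_id,
                     chromosomes = as.data.frame(tr$chromosomes),
                     segments = segs, purity = tr$purity,
                     men1_somatic = tr$men1_somatic,
                     group = as.integer(tr$group)),
                class = "karyotype_truth")
    })
    names(truths) <- vapply(truths, `[[`, character(1), "tumor_id")
  }
  ids <- sort(unique(sub("\\.normal\\.tiles\\.tsv$", "",
                         list.files(dir, "\\.normal\\.tiles\\.tsv$"))))
  tumors <- lapply(ids, function(id) {
    p <- function(x) file.path(dir, paste0(id, x))
    vars <- read_variants(p(".variants.vcf"))
    list(normal_tiles = read_tile_track(p(".normal.tiles.tsv")),
         tumor_tiles = read_tile_track(p(".tumor.tiles.tsv")),
         normal_alleles = read_allele_counts(p(".normal.alleles.tsv")),
         tumor_alleles = read_allele_counts(p(".tumor.alleles.tsv")),
         somatic = vars[vars$origin == "somatic", , drop = FALSE],
         germline = vars[vars$origin == "germline", , drop = FALSE])
  })
  names(tumors) <- ids
  expression <- NULL
  expr_path <- file.path(dir, "expression.tsv")
  if (file.exists(expr_path)) {
    df <- utils::read.delim(expr_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    genes <- df[, c("gene_id", "chrom", "start", "end")]
    vals <- as.matrix(df[, setdiff(names(df), names(genes)), drop = FALSE])
    rownames(vals) <- genes$gene_id
    batch <- NULL
    bpath <- file.path(dir, "batches.txt")
    if (file.exists(bpath)) {
      line <- sub("^# batch labels: ", "", readLines(bpath, n = 1))
      kv <- strsplit(strsplit(line, ",")[[1]], "=")
      batch <- stats::setNames(vapply(kv, `[`, character(1), 2),
                               vapply(kv, `[`, character(1), 1))
    }
    expression <- expression_matrix(vals, genes, batch)
  }
  clin_path <- file.path(dir, "clinical.tsv")
  clinical <- if (file.exists(clin_path)) {
    utils::read.delim(clin_path, stringsAsFactors = FALSE)
  } else NULL
  bl_path <- file.path(dir, "blacklist.bed")
  blacklist <- if (file.exists(bl_path)) {
    bl <- utils::read.delim(bl_path, header = FALSE,
                            stringsAsFactors = FALSE)[, 1:3]
    names(bl) <- c("chrom", "start", "end")
    bl
  } else NULL
  structure(list(genome = genome, truths = truths, tumors = tumors,
                 expression = expression, clinical = clinical,
                 blacklist = blacklist, config = cfg),
            class = "sim_cohort")
}
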