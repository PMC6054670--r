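# Expression-matrix transforms and copy-number dosage analysis at
# chromosome and segment scale.

#' Construct an expression matrix object
#'
#' @param values Gene x sample numeric matrix on log2 scale (rownames =
#'   gene ids).
#' @param genes Gene coordinate data.frame (gene_id, chrom, start, end;
#'   1-based inclusive).
#' @param batch Named character vector of batch labels per sample.
#' @return List of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values, genes, batch = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (!all(rownames(values) %in% genes$gene_id)) {
    stop("all genes in the matrix need coordinates")
  }
  if (is.null(batch)) {
    batch <- stats::setNames(rep("batch1", ncol(values)), colnames(values))
  }
  stopifnot(all(colnames(values) %in% names(batch)))
  structure(list(values = values,
                 genes = genes[match(rownames(values), genes$gene_id), ],
                 batch = batch[colnames(values)]),
            class = "expression_matrix")
}

#' Remove additive batch effects by within-batch gene centering
#'
#' For every gene, the mean signal within each batch is subtracted from that
#' batch's samples, so per-gene per-batch means become zero and any additive
#' batch offset (e.g. an archival-vs-frozen preservation split) is removed.
#'
#' @param mat An \code{expression_matrix}.
#' @return The matrix, batch-centered.
#' @export
batch_center <- function(mat) {
  v <- mat$values
  for (b in unique(mat$batch)) {
    cols <- which(mat$batch == b)
    if (length(cols) < 2) {
      stop("batch '", b, "' has a single sample; centering would zero it")
    }
    v[, cols] <- v[, cols] - rowMeans(v[, cols, drop = FALSE])
  }
  mat$values <- v
  mat
}

#' Gene-wise Z-score transform across the cohort
#'
#' Per gene: subtract the cohort mean and divide by the sample standard
#' deviation (n - 1). Zero-variance genes get Z = 0 and are flagged.
#'
#' @param mat An \code{expression_matrix} with >= 3 samples.
#' @return The matrix Z-scored, with attribute \code{zero_variance_genes}.
#' @export
zscore <- function(mat) {
  v <- mat$values
  if (ncol(v) < 3) stop("Z-scoring needs >= 3 samples")
  mu <- rowMeans(v)
  sd_g <- apply(v, 1, stats::sd)
  flat <- sd_g == 0 | !is.finite(sd_g)
  z <- (v - mu) / ifelse(flat, 1, sd_g)
  z[flat, ] <- 0
  mat$values <- z
  attr(mat, "zero_variance_genes") <- rownames(v)[flat]
  mat
}

#' Mean expression per chromosome per sample
#'
#' Genes are assigned to chromosomes by their midpoint. Chromosomes with
#' fewer than \code{min_genes} genes are flagged; chromosomes with none are
#' omitted with a warning.
#'
#' @param mat An \code{expression_matrix}.
#' @param min_genes Flagging threshold (default 5).
#' @return Matrix chromosome x sample of mean expression, with attribute
#'   \code{n_genes}.
#' @export
chromosome_mean_expression <- function(mat, min_genes = 5) {
  chrom <- mat$genes$chrom
  means <- apply(mat$values, 2, function(col) tapply(col, chrom, mean))
  n_genes <- tapply(chrom, chrom, length)
  means <- means[order(chrom_rank(rownames(means))), , drop = FALSE]
  n_genes <- n_genes[rownames(means)]
  if (any(n_genes < min_genes)) {
    attr(means, "flagged") <- rownames(means)[n_genes < min_genes]
  }
  attr(means, "n_genes") <- n_genes
  means
}

#' Per-tumor Pearson correlation between chromosome CN and mean expression
#'
#' @param karyotype A \code{karyotype} object.
#' @param chrom_means Named vector (chromosome -> mean expression) for the
#'   same tumor, e.g. one column of [chromosome_mean_expression()].
#' @return Pearson r, or NA (flagged euploid) when CN is constant across
#'   chromosomes -- correlation is undefined there, and such tumors are
#'   excluded from cohort histograms rather than assigned r = 0.
#' @export
cn_expression_correlation <- function(karyotype, chrom_means) {
  common <- intersect(karyotype$calls$chrom, names(chrom_means))
  if (length(common) < 3) stop("need >= 3 chromosomes with CN and expression")
  cn <- karyotype$calls$dominant_cn[match(common, karyotype$calls$chrom)]
  expr <- chrom_means[common]
  if (stats::sd(cn) == 0) {
    return(structure(NA_real_, euploid = TRUE))
  }
  stats::cor(cn, expr, method = "pearson")
}

#' Mean expression within copy-number segments
#'
#' A gene contributes to the segment containing its midpoint. Segments with
#' fewer than \code{min_genes} genes are flagged; empty segments get NA.
#'
#' @param segments A \code{cn_segments} data.frame for one tumor.
#' @param mat An \code{expression_matrix}.
#' @param tumor Sample id (column of the matrix).
#' @param min_genes Flagging threshold (default 3).
#' @return Segments with columns \code{mean_expr}, \code{n_genes},
#'   \code{expr_flagged}.
#' @export
segment_mean_expression <- function(segments, mat, tumor, min_genes = 3) {
  vals <- mat$values[, tumor]
  mid <- (mat$genes$start + mat$genes$end) / 2
  segments$mean_expr <- NA_real_
  segments$n_genes <- NA_integer_
  for (k in seq_len(nrow(segments))) {
    hit <- mat$genes$chrom == segments$chrom[k] & mid > segments$start[k] &
      mid <= segments$end[k]
    segments$n_genes[k] <- sum(hit)
    if (any(hit)) segments$mean_expr[k] <- mean(vals[hit])
  }
  segments$expr_flagged <- segments$n_genes < min_genes
  segments
}

#' Compare chromosome mean expression between loss and intact tumors
#'
#' Two-sided Mann-Whitney U test of per-tumor mean expression of one
#' chromosome, tumors with whole-chromosome loss (LoH with dominant CN
#' below 2, or any LoH when \code{loss = "loh"}) versus tumors with the
#' chromosome intact. Exact p-values when the smaller group has at most 8
#' tumors and there are no ties; normal approximation with tie correction
#' otherwise.
#'
#' @param chrom_means Chromosome x sample matrix from
#'   [chromosome_mean_expression()].
#' @param karyotypes List of \code{karyotype} objects (ids matching matrix
#'   columns).
#' @param chromosome Chromosome to test, e.g. "chr11".
#' @param loss Definition of the loss group: \code{"monosomy"} (LoH and
#'   dominant CN <= 1) or \code{"loh"} (any LoH; default).
#' @param min_per_group Minimum tumors per group (default 3).
#' @return List with p-value, U statistic, group means and sizes, direction.
#' @export
compare_loss_vs_intact <- function(chrom_means, karyotypes, chromosome,
                                   loss = c("loh", "monosomy"),
                                   min_per_group = 3) {
  loss <- match.arg(loss)
  ids <- vapply(karyotypes, `[[`, character(1), "tumor_id")
  ids <- intersect(ids, colnames(chrom_means))
  state <- vapply(karyotypes[match(ids, vapply(karyotypes, `[[`,
                                               character(1), "tumor_id"))],
                  function(k) {
    row <- k$calls[k$calls$chrom == chromosome, ]
    if (!nrow(row) || is.na(row$loh)) return(NA)
    if (loss == "loh") row$loh else row$loh && row$dominant_cn <= 1
  }, logical(1))
  expr <- chrom_means[chromosome, ids]
  lost <- expr[state %in% TRUE]
  intact <- expr[state %in% FALSE]
  if (length(lost) < min_per_group || length(intact) < min_per_group) {
    stop("need >= ", min_per_group, " tumors in both loss and intact groups")
  }
  exact <- min(length(lost), length(intact)) <= 8 &&
    !any(duplicated(c(lost, intact)))
  wt <- stats::wilcox.test(lost, intact, alternative = "two.sided",
                           exact = exact, correct = !exact)
  list(p = wt$p.value, U = unname(wt$statistic),
       mean_loss = mean(lost), mean_intact = mean(intact),
       n_loss = length(lost), n_intact = length(intact),
       direction = if (mean(lost) < mean(intact)) "reduced" else "elevated")
}
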