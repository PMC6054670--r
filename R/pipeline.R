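# Orchestration: het calling -> log ratios -> CBS -> CN/LoH karyotype ->
# variant rules -> group classification -> dosage analysis, with a cohort
# report and optional truth-vs-called comparison.

#' Analyze one tumor/normal pair
#'
#' Runs the DNA stages for a single tumor: germline het calling, tumor BAF,
#' normalized log ratios (blacklist-masked, outlier-smoothed), CBS, integer
#' CN assignment, segment and chromosome LoH calls, somatic variant
#' filtering, MEN1 status and unopposed germline variants.
#'
#' @param tumor Per-tumor input list (normal_tiles, tumor_tiles,
#'   normal_alleles, tumor_alleles, somatic, germline) as produced by
#'   [simulate_counts()]/[simulate_variants()] or [load_cohort()].
#' @param genome A \code{genome_model} (for gene annotation).
#' @param purity Tumor purity in (0, 1] (default 0.5).
#' @param tumor_id Sample identifier.
#' @param params List of stage parameters overriding defaults (min_depth,
#'   baf_lo, baf_hi, confidence, loess_frac, min_normal, alpha, n_perm,
#'   min_width, merge_tol, max_cn, min_hets, loh_frac, filter thresholds,
#'   ratio_min).
#' @param blacklist Optional blacklist data.frame.
#' @param seed Integer seed for the segmentation permutations.
#' @return List with hets, log_ratio, segments, karyotype, variants
#'   (filter audit), men1_status, unopposed.
#' @export
analyze_tumor <- function(tumor, genome, purity = 0.5,
                          tumor_id = NA_character_, params = list(),
                          blacklist = NULL, seed = 1L) {
  p <- utils::modifyList(default_params(), params)
  hets <- call_germline_hets(tumor$normal_alleles, baf_lo = p$baf_lo,
                             baf_hi = p$baf_hi, confidence = p$confidence,
                             min_depth = p$min_depth)
  hets <- tumor_baf(hets, tumor$tumor_alleles, min_depth = p$min_depth)
  lr <- tile_log_ratio(tumor$tumor_tiles, tumor$normal_tiles,
                       loess_frac = p$loess_frac, min_normal = p$min_normal)
  lr <- apply_blacklist(lr, blacklist)
  lr <- smooth_outliers(lr, window = p$smooth_window, z_cap = p$z_cap)
  segs <- cbs_segment(lr, alpha = p$alpha, n_perm = p$n_perm,
                      min_width = p$min_width, merge_tol = p$merge_tol,
                      seed = seed)
  segs <- recenter_segments(segs, tol = p$recenter_tol)
  segs <- assign_segment_cn(segs, purity, max_cn = p$max_cn)
  segs <- segment_loh(segs, hets, purity, min_hets = p$min_hets)
  kar <- build_karyotype(segs, tumor_id, loh_frac = p$loh_frac)
  fcfg <- filter_config(min_depth = p$min_depth,
                        min_tumor_alt = p$min_tumor_alt,
                        max_normal_alt = p$max_normal_alt,
                        blacklist = blacklist)
  flt <- if (!is.null(tumor$somatic) && nrow(tumor$somatic)) {
    filter_somatic(tumor$somatic, fcfg)
  } else NULL
  men1 <- if (!is.null(flt)) {
    biallelic_inactivation("MEN1", flt$pass, kar, genome$genes,
                           segments = segs)
  } else "wild_type"
  unop <- if (!is.null(tumor$germline) && nrow(tumor$germline)) {
    unopposed_germline(tumor$germline, kar, purity,
                       ratio_min = p$ratio_min, segments = segs)
  } else NULL
  list(tumor_id = tumor_id, hets = hets, log_ratio = lr, segments = segs,
       karyotype = kar, variants = flt, men1_status = men1,
       unopposed = unop)
}

default_params <- function() {
  list(min_depth = 50, baf_lo = 0.4, baf_hi = 0.6, confidence = 0.95,
       loess_frac = 0.3, min_normal = 10, smooth_window = 5, z_cap = 3,
       alpha = 0.01, n_perm = 1000, min_width = 3, merge_tol = 0.05,
       max_cn = 8, recenter_tol = 0.1, min_hets = 10, loh_frac = 0.8,
       min_tumor_alt = 10, max_normal_alt = 2, ratio_min = 1.5,
       high_loh_min = 8, member_freq = 0.8, min_overlap = 0.8)
}

#' Run the full cohort pipeline
#'
#' Input is either an in-memory cohort (from [simulate_cohort()]) or a
#' directory written by [write_cohort()]. Per-tumor purity is taken from
#' \code{purity} (named vector), else from the cohort truth records, else
#' defaults to 0.5. The report contains the karyotype matrix, aneuploidy
#' summary, group assignments, clinical associations, variant audit tables,
#' dosage correlations and -- when truth is available -- truth-vs-called
#' comparisons. Deterministic given \code{seed}.
#'
#' @param cohort A \code{sim_cohort} or a directory path.
#' @param params Stage-parameter overrides (see [analyze_tumor()]).
#' @param purity Optional named numeric vector of per-tumor purities.
#' @param seed Integer seed.
#' @param use_truth_purity Take purities from truth records when no
#'   explicit value is supplied (default TRUE).
#' @return List of class \code{cohort_report}.
#' @export
run_pipeline <- function(cohort, params = list(), purity = NULL, seed = 1L,
                         use_truth_purity = TRUE) {
  if (is.character(cohort)) cohort <- load_cohort(cohort)
  p <- utils::modifyList(default_params(), params)
  ids <- names(cohort$tumors)
  results <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    rho <- if (!is.null(purity) && id %in% names(purity)) {
      purity[[id]]
    } else if (use_truth_purity && !is.null(cohort$truths)) {
      cohort$truths[[id]]$purity
    } else 0.5
    results[[i]] <- analyze_tumor(
      cohort$tumors[[id]], cohort$genome, purity = rho, tumor_id = id,
      params = params, blacklist = cohort$blacklist,
      seed = (as.integer(seed) + i) %% 2147483629
    )
  }
  names(results) <- ids
  karyotypes <- lapply(results, `[[`, "karyotype")
  aneuploidy <- cohort_aneuploidy_summary(karyotypes)
  rec <- mine_recurrent_loh(karyotypes, high_loh_min = p$high_loh_min,
                            member_freq = p$member_freq)
  men1 <- vapply(results, function(r) {
    r$men1_status %in% c("biallelic", "monoallelic")
  }, logical(1))
  names(men1) <- ids
  groups <- classify_groups(karyotypes, men1, rec,
                            min_overlap = p$min_overlap)
  assoc <- if (!is.null(cohort$clinical)) {
    associate_clinical(groups, cohort$clinical)
  } else NULL
  dosage <- if (!is.null(cohort$expression)) {
    run_dosage(cohort$expression, karyotypes)
  } else {
    warning("no expression matrix; dosage stage skipped")
    NULL
  }
  truth_cmp <- if (!is.null(cohort$truths)) {
    compare_to_truth(results, groups, cohort$truths)
  } else NULL
  structure(list(
    results = results, karyotype_matrix = karyotype_matrix(karyotypes),
    aneuploidy = aneuploidy, recurrent_set = rec, groups = groups,
    clinical_association = assoc, dosage = dosage, truth = truth_cmp,
    params = p, seed = as.integer(seed)
  ), class = "cohort_report")
}

run_dosage <- function(expression, karyotypes) {
  mat <- batch_center(expression)
  cm <- chromosome_mean_expression(mat)
  ids <- intersect(colnames(cm),
                   vapply(karyotypes, `[[`, character(1), "tumor_id"))
  kar_by_id <- stats::setNames(
    karyotypes, vapply(karyotypes, `[[`, character(1), "tumor_id"))
  r <- vapply(ids, function(id) {
    cn_expression_correlation(kar_by_id[[id]], cm[, id])
  }, numeric(1))
  chr11 <- tryCatch(
    compare_loss_vs_intact(cm, karyotypes, "chr11", loss = "loh"),
    error = function(e) {
      warning("chr11 loss-vs-intact comparison skipped: ",
              conditionMessage(e))
      NULL
    })
  list(chrom_means = cm, correlations = r, chr11 = chr11)
}

compare_to_truth <- function(results, groups, truths) {
  per_chrom <- do.call(rbind, lapply(names(results), function(id) {
    k <- results[[id]]$karyotype$calls
    tr <- truths[[id]]$chromosomes
    m <- merge(k, tr, by = "chrom", suffixes = c("_called", "_true"))
    data.frame(tumor_id = id, chrom = m$chrom,
               cn_called = m$dominant_cn, cn_true = m$cn,
               loh_called = m$loh_called, loh_true = m$loh_true %in% TRUE,
               stringsAsFactors = FALSE)
  }))
  known <- !is.na(per_chrom$loh_called)
  cn_acc <- mean(per_chrom$cn_called == per_chrom$cn_true)
  sens_den <- sum(per_chrom$loh_true & known)
  spec_den <- sum(!per_chrom$loh_true & known)
  true_group <- vapply(truths[groups$tumor_id], `[[`, integer(1), "group")
  list(
    per_chrom = per_chrom,
    cn_accuracy = cn_acc,
    loh_sensitivity = if (sens_den) {
      sum(per_chrom$loh_true & known & per_chrom$loh_called) / sens_den
    } else NA_real_,
    loh_specificity = if (spec_den) {
      sum(!per_chrom$loh_true & known & !per_chrom$loh_called) / spec_den
    } else NA_real_,
    loh_unknown_fraction = mean(!known),
    group_agreement = mean(groups$group == true_group),
    group_confusion = table(called = groups$group, truth = true_group)
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  fr <- x$aneuploidy$fractions
  cat("cohort report:", nrow(x$groups), "tumors\n")
  cat(sprintf("  >=1 monosomy: %.0f%%  >=1 LoH: %.0f%%  >=8 LoH: %.0f%%\n",
              100 * fr["monosomy_ge1"], 100 * fr["loh_ge1"],
              100 * fr["loh_ge8"]))
  cat("  recurrent LoH set:",
      if (length(x$recurrent_set$chromosomes)) {
        paste(x$recurrent_set$chromosomes, collapse = " ")
      } else "(none)", "\n")
  cat("  groups:", paste(sprintf("%d x Group %s", table(x$groups$group),
                                 names(table(x$groups$group))),
                         collapse = ", "), "\n")
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: CN acc %.3f, LoH sens %.3f / spec %.3f, group agr %.3f\n",
                x$truth$cn_accuracy, x$truth$loh_sensitivity,
                x$truth$loh_specificity, x$truth$group_agreement))
  }
  invisible(x)
}
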