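# Integration of segment copy number and het-site allelic imbalance into
# per-segment and per-autosome LoH calls, dominant CN, and cohort summaries.

#' LoH evidence threshold at a given purity
#'
#' Half the mirrored-BAF deviation expected for a one-copy loss at purity
#' \eqn{\rho}: \eqn{\theta(\rho) = (1/(2-\rho) - 1/2)/2}. Mean deviations at
#' or above this are called LoH; the halving keeps copy-neutral LoH (whose
#' deviation \eqn{\rho/2} is larger) well inside the calling region while
#' leaving headroom for sampling noise on balanced segments.
#'
#' @param purity Tumor purity in (0, 1].
#' @return Threshold on the mean mirrored BAF deviation.
#' @export
loh_threshold <- function(purity) {
  (expected_baf(purity, 1, 1) - 0.5) / 2
}

#' Call LoH per segment from het-site BAF deviations
#'
#' Each segment's het sites (from [tumor_baf()]) contribute their mirrored
#' BAF deviation; the segment is LoH when the mean deviation reaches
#' [loh_threshold()] and at least \code{min_hets} sites support it. Segments
#' with fewer sites inherit the chromosome-level fallback call (all het
#' sites of the chromosome pooled); chromosomes with no het sites get
#' \code{loh = NA}.
#'
#' @param segments A \code{cn_segments} data.frame (bp coordinates 0-based
#'   half-open).
#' @param hets Het sites with tumor evidence (columns chrom, pos, d).
#' @param purity Tumor purity in (0, 1].
#' @param min_hets Minimum informative sites per segment (default 10).
#' @return Segments with \code{baf_dev}, \code{n_hets}, \code{loh} filled.
#' @export
segment_loh <- function(segments, hets, purity, min_hets = 10) {
  theta <- loh_threshold(purity)
  chrom_dbar <- tapply(hets$d, hets$chrom, mean)
  chrom_n <- tapply(hets$d, hets$chrom, length)
  for (k in seq_len(nrow(segments))) {
    ch <- segments$chrom[k]
    in_seg <- hets$chrom == ch & hets$pos > segments$start[k] &
      hets$pos <= segments$end[k]
    n <- sum(in_seg)
    segments$n_hets[k] <- n
    if (n >= min_hets) {
      dbar <- mean(hets$d[in_seg])
      segments$baf_dev[k] <- dbar
      segments$loh[k] <- dbar >= theta
    } else if (!is.na(chrom_n[ch]) && chrom_n[ch] >= min_hets) {
      # chromosome-level fallback for sparse segments
      segments$baf_dev[k] <- unname(chrom_dbar[ch])
      segments$loh[k] <- unname(chrom_dbar[ch]) >= theta
    } else {
      segments$baf_dev[k] <- NA_real_
      segments$loh[k] <- NA
    }
  }
  segments
}

#' Roll segments of one chromosome up to a chromosome-level call
#'
#' Dominant CN is the bp-length-weighted mode of segment CN;
#' \code{support_fraction} is the bp fraction backing it. The chromosome is
#' called whole-chromosome LoH when at least \code{loh_frac} of its bp lies
#' in LoH segments (partial LoH shows up as \code{heterogeneous} instead).
#' \code{heterogeneous} is set when more than one CN state each covers at
#' least 20% of the chromosome.
#'
#' @param segments Segments of a single chromosome with \code{cn} and
#'   \code{loh} filled.
#' @param loh_frac bp fraction required for a whole-chromosome LoH call
#'   (default 0.8).
#' @return One-row data.frame: chrom, dominant_cn, loh, support_fraction,
#'   heterogeneous.
#' @export
chromosome_call <- function(segments, loh_frac = 0.8) {
  stopifnot(nrow(segments) >= 1, length(unique(segments$chrom)) == 1)
  len <- segments$end - segments$start
  total <- sum(len)
  by_cn <- tapply(len, segments$cn, sum)
  dominant_cn <- as.integer(names(by_cn)[which.max(by_cn)])
  support <- max(by_cn) / total
  hetero <- sum(by_cn / total >= 0.2) > 1
  loh_known <- !is.na(segments$loh)
  loh <- if (!any(loh_known)) {
    NA
  } else {
    sum(len[loh_known & segments$loh %in% TRUE]) / total >= loh_frac
  }
  data.frame(chrom = segments$chrom[1], dominant_cn = dominant_cn,
             loh = loh, support_fraction = support,
             heterogeneous = hetero, stringsAsFactors = FALSE)
}

new_karyotype <- function(tumor_id, calls) {
  loh_known <- !is.na(calls$loh)
  structure(list(
    tumor_id = tumor_id,
    calls = calls,
    n_monosomic = sum(calls$loh %in% TRUE & calls$dominant_cn == 1),
    n_loh = sum(calls$loh %in% TRUE),
    n_unknown = sum(!loh_known)
  ), class = "karyotype")
}

#' Build a whole-genome karyotype from segments
#'
#' Applies [chromosome_call()] to every chromosome and computes the
#' monosomy/LoH tallies: \code{n_monosomic} counts chromosomes with LoH at
#' dominant CN 1, \code{n_loh} counts LoH of any CN (so copy-neutral LoH is
#' included). Chromosomes with unknown LoH (no het sites) are excluded from
#' both tallies and counted in \code{n_unknown}.
#'
#' @param segments Full \code{cn_segments} with \code{cn} and \code{loh}.
#' @param tumor_id Sample identifier.
#' @param loh_frac Passed to [chromosome_call()].
#' @return Object of class \code{karyotype}.
#' @export
build_karyotype <- function(segments, tumor_id = NA_character_,
                            loh_frac = 0.8) {
  calls <- do.call(rbind, lapply(split(segments, segments$chrom),
                                 chromosome_call, loh_frac = loh_frac))
  ord <- order(chrom_rank(calls$chrom))
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  new_karyotype(tumor_id, calls)
}

chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.integer(sub("^chr", "", chrom)))
  ifelse(is.na(num), rank(chrom) + 1e6, num)
}

#' @export
print.karyotype <- function(x, ...) {
  cat("karyotype of", x$tumor_id, "-", nrow(x$calls), "chromosomes;",
      x$n_monosomic, "monosomic,", x$n_loh, "with LoH\n")
  invisible(x)
}

#' Cohort aneuploidy summary
#'
#' Per-tumor monosomy and LoH counts plus the cohort fractions with at least
#' one monosomic chromosome, at least one LoH chromosome, and LoH of eight
#' or more chromosomes.
#'
#' @param karyotypes List of \code{karyotype} objects.
#' @return List with \code{per_tumor} (data.frame tumor_id, n_monosomic,
#'   n_loh) and \code{fractions} (named vector monosomy_ge1, loh_ge1,
#'   loh_ge8).
#' @export
cohort_aneuploidy_summary <- function(karyotypes) {
  stopifnot(length(karyotypes) >= 1)
  per <- data.frame(
    tumor_id = vapply(karyotypes, `[[`, character(1), "tumor_id"),
    n_monosomic = vapply(karyotypes, `[[`, integer(1), "n_monosomic"),
    n_loh = vapply(karyotypes, `[[`, integer(1), "n_loh"),
    stringsAsFactors = FALSE
  )
  list(per_tumor = per,
       fractions = c(monosomy_ge1 = mean(per$n_monosomic >= 1),
                     loh_ge1 = mean(per$n_loh >= 1),
                     loh_ge8 = mean(per$n_loh >= 8)))
}

#' Karyotype matrix for a cohort
#'
#' Tumor-by-chromosome table of dominant CN and LoH flags, the exchange
#' format consumed by group classification.
#'
#' @param karyotypes List of \code{karyotype} objects.
#' @return data.frame with tumor_id, chrom, dominant_cn, loh.
#' @export
karyotype_matrix <- function(karyotypes) {
  do.call(rbind, lapply(karyotypes, function(k) {
    cbind(tumor_id = k$tumor_id, k$calls[, c("chrom", "dominant_cn", "loh")],
          stringsAsFactors = FALSE)
  }))
}
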