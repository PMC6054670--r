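# Germline heterozygote detection and tumor B-allele-frequency evidence.

#' Exact two-sided binomial test of allelic balance
#'
#' Probability, under Binomial(n, 1/2), of observing an ALT count whose point
#' mass is no larger than that of the observed count -- the standard two-sided
#' exact test against the null that ALT and REF reads are equally common.
#' Symmetric: \code{p(k, n) == p(n - k, n)}.
#'
#' @param n_alt ALT read count(s), 0..n.
#' @param n Total depth(s), >= 1.
#' @return Two-sided p-value(s) in (0, 1]. Vectorized; recycled to common
#'   length.
#' @export
binomial_equal_allele_p <- function(n_alt, n) {
  len <- max(length(n_alt), length(n))
  n_alt <- rep_len(as.numeric(n_alt), len)
  n <- rep_len(as.numeric(n), len)
  if (any(is.na(n_alt)) || any(is.na(n))) stop("NA counts")
  if (any(n < 1)) stop("depth n must be >= 1")
  if (any(n_alt < 0 | n_alt > n)) stop("need 0 <= n_alt <= n")
  p <- vapply(seq_len(len), function(i) {
    k <- n_alt[i]
    ni <- n[i]
    mass <- dbinom(0:ni, ni, 0.5)
    # relative tolerance guards against ties broken by floating point noise
    sum(mass[mass <= mass[k + 1] * (1 + 1e-7)])
  }, numeric(1))
  pmin(p, 1)
}

#' Allele count table constructor/validator
#'
#' @param chrom,pos,ref,alt,ref_count,alt_count Per-site fields; \code{pos} is
#'   1-based.
#' @param sample_id Sample identifier attached as an attribute.
#' @return A \code{data.frame} of class \code{allele_counts}.
#' @export
allele_counts <- function(chrom, pos, ref = "A", alt = "G",
                          ref_count, alt_count, sample_id = NA_character_) {
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    ref_count = as.integer(ref_count), alt_count = as.integer(alt_count),
    stringsAsFactors = FALSE
  )
  if (any(df$ref_count < 0) || any(df$alt_count < 0)) stop("negative counts")
  if (anyDuplicated(df[, c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) in allele count table")
  }
  attr(df, "sample_id") <- sample_id
  class(df) <- c("allele_counts", class(df))
  df
}

#' Call germline heterozygous sites
#'
#' A site is called heterozygous when (i) its germline ALT read fraction lies
#' strictly inside \code{(baf_lo, baf_hi)}, (ii) the balanced-allele null is
#' compatible with the observed counts at the stated confidence (by default:
#' the exact two-sided binomial p-value is at least \code{1 - confidence}),
#' and (iii) site depth is at least \code{min_depth}.
#'
#' @param germline An \code{allele_counts} table for the germline sample.
#' @param baf_lo,baf_hi Open BAF interval bounds (defaults 0.4 and 0.6).
#' @param confidence Confidence level of the compatibility criterion
#'   (default 0.95, i.e. p >= 0.05).
#' @param min_depth Minimum site depth (default 50).
#' @param mode Reading of the compatibility criterion:
#'   \code{"not_rejected"} (default) keeps sites whose two-sided p-value is
#'   \code{>= 1 - confidence}; \code{"literal"} requires the p-value itself to
#'   be \code{>= confidence}, a much stricter reading that rejects most true
#'   heterozygotes and is provided for comparison only.
#' @return A \code{data.frame} of het sites (chrom, pos, depth, baf, p_het),
#'   sorted by (chrom, pos).
#' @export
call_germline_hets <- function(germline, baf_lo = 0.4, baf_hi = 0.6,
                               confidence = 0.95, min_depth = 50,
                               mode = c("not_rejected", "literal")) {
  mode <- match.arg(mode)
  stopifnot(nrow(germline) > 0)
  depth <- germline$ref_count + germline$alt_count
  keep_depth <- depth >= min_depth & depth > 0
  baf <- ifelse(depth > 0, germline$alt_count / depth, NA_real_)
  in_band <- !is.na(baf) & baf > baf_lo & baf < baf_hi
  cand <- which(keep_depth & in_band)
  p <- rep(NA_real_, nrow(germline))
  if (length(cand)) {
    p[cand] <- binomial_equal_allele_p(germline$alt_count[cand], depth[cand])
  }
  thr <- if (mode == "not_rejected") 1 - confidence else confidence
  het <- !is.na(p) & p >= thr
  out <- data.frame(
    chrom = germline$chrom[het], pos = germline$pos[het],
    depth = depth[het], baf = baf[het], p_het = p[het],
    stringsAsFactors = FALSE
  )
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Attach tumor BAF evidence to called het sites
#'
#' Joins tumor allele counts onto germline het sites and computes the tumor
#' BAF \code{baf_t} and the mirrored BAF deviation \code{d = |baf_t - 0.5|},
#' the allelic-imbalance statistic used for LoH calling (agnostic to which
#' allele is retained). Sites absent from the tumor table, or with tumor depth
#' below \code{min_depth}, are dropped.
#'
#' @param hets Het-site table from [call_germline_hets()].
#' @param tumor An \code{allele_counts} table for the tumor sample.
#' @param min_depth Minimum tumor depth (default 50).
#' @return Het sites with columns \code{t_depth}, \code{baf_t}, \code{d}.
#' @export
tumor_baf <- function(hets, tumor, min_depth = 50) {
  key_h <- paste(hets$chrom, hets$pos)
  key_t <- paste(tumor$chrom, tumor$pos)
  idx <- match(key_h, key_t)
  t_depth <- tumor$ref_count[idx] + tumor$alt_count[idx]
  keep <- !is.na(idx) & t_depth >= min_depth & t_depth > 0
  if (!any(keep)) {
    warning("no het sites covered in tumor sample at required depth")
  }
  out <- hets[keep, , drop = FALSE]
  out$t_depth <- t_depth[keep]
  out$baf_t <- tumor$alt_count[idx[keep]] / t_depth[keep]
  out$d <- abs(out$baf_t - 0.5)
  rownames(out) <- NULL
  out
}

#' Read an allele count table from TSV or minimal VCF
#'
#' TSV input must have columns chrom, pos, ref, alt, ref_count, alt_count.
#' VCF input must carry an AD (allelic depths) FORMAT field; only the first
#' ALT allele is used and multi-allelic records beyond it are dropped with a
#' warning.
#'
#' @param path File path (.vcf or tab-separated text).
#' @param sample For VCF input, the sample column to read (default: first).
#' @return An \code{allele_counts} table.
#' @export
read_allele_counts <- function(path, sample = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ad <- vcfR::extract.gt(v, element = "AD")
    if (is.null(sample)) sample <- colnames(ad)[1]
    ad_s <- ad[, sample]
    parts <- strsplit(ad_s, ",", fixed = TRUE)
    multi <- grepl(",", vcfR::getALT(v), fixed = TRUE)
    if (any(multi)) {
      warning(sum(multi), " multi-allelic site(s): only first ALT used")
    }
    allele_counts(
      chrom = vcfR::getCHROM(v), pos = vcfR::getPOS(v),
      ref = vcfR::getREF(v),
      alt = vapply(strsplit(vcfR::getALT(v), ","), `[`, character(1), 1),
      ref_count = vapply(parts, function(x) as.integer(x[1]), integer(1)),
      alt_count = vapply(parts, function(x) as.integer(x[2]), integer(1)),
      sample_id = sample
    )
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "ref_count", "alt_count")
    if (!all(need %in% names(df))) {
      stop("allele count TSV needs columns: ", paste(need, collapse = ", "))
    }
    allele_counts(df$chrom, df$pos, df$ref, df$alt,
                  df$ref_count, df$alt_count,
                  sample_id = sub("\\..*$", "", basename(path)))
  }
}
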