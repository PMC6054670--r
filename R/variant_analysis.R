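# Post-calling somatic variant filters, unopposed germline variant
# detection, biallelic inactivation calls, and coding mutation rates.

#' Somatic variant filter configuration
#'
#' Post-calling thresholds: read depth at the site of at least
#' \code{min_depth} in both tumor and normal, at least \code{min_tumor_alt}
#' tumor reads showing the mutation, at most \code{max_normal_alt} supporting
#' reads in the germline sample, and exclusion of blacklisted regions.
#'
#' @param min_depth Minimum depth in both samples (default 50).
#' @param min_tumor_alt Minimum tumor ALT reads (default 10).
#' @param max_normal_alt Maximum germline ALT reads (default 2).
#' @param blacklist Optional data.frame (chrom, start, end; 0-based
#'   half-open) of excluded regions.
#' @return List of class \code{filter_config}.
#' @export
filter_config <- function(min_depth = 50, min_tumor_alt = 10,
                          max_normal_alt = 2, blacklist = NULL) {
  stopifnot(min_depth >= 0, min_tumor_alt >= 0, max_normal_alt >= 0)
  structure(list(min_depth = min_depth, min_tumor_alt = min_tumor_alt,
                 max_normal_alt = max_normal_alt, blacklist = blacklist),
            class = "filter_config")
}

in_blacklist <- function(chrom, pos, blacklist) {
  if (is.null(blacklist) || !nrow(blacklist)) {
    return(rep(FALSE, length(chrom)))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  bl <- GenomicRanges::GRanges(blacklist$chrom,
                               IRanges::IRanges(blacklist$start + 1,
                                                blacklist$end))
  suppressWarnings(GenomicRanges::countOverlaps(q, bl)) > 0
}

#' Apply post-calling filters to somatic variant candidates
#'
#' Audit-friendly: every record is returned with its full set of fail
#' reasons; passing records have none. The filter is idempotent and
#' order-independent.
#'
#' @param variants data.frame with columns chrom, pos (1-based), t_ref,
#'   t_alt, n_ref, n_alt (tumor/normal allelic depths).
#' @param cfg A [filter_config()].
#' @return List with \code{pass} (passing subset), \code{fail} (failing
#'   subset with \code{reasons}), and \code{audited} (all records with
#'   \code{pass} flag and \code{reasons} string).
#' @export
filter_somatic <- function(variants, cfg = filter_config()) {
  v <- variants
  need <- c("chrom", "pos", "t_ref", "t_alt", "n_ref", "n_alt")
  if (!all(need %in% names(v))) {
    stop("variant table needs columns: ", paste(need, collapse = ", "))
  }
  t_depth <- v$t_ref + v$t_alt
  n_depth <- v$n_ref + v$n_alt
  malformed <- is.na(t_depth) | is.na(n_depth) | is.na(v$pos) |
    v$t_ref < 0 | v$t_alt < 0 | v$n_ref < 0 | v$n_alt < 0
  reasons <- vector("list", nrow(v))
  add <- function(reasons, which, tag) {
    for (i in which(which)) reasons[[i]] <- c(reasons[[i]], tag)
    reasons
  }
  reasons <- add(reasons, malformed, "malformed")
  ok <- !malformed
  reasons <- add(reasons, ok & t_depth < cfg$min_depth, "tumor_depth")
  reasons <- add(reasons, ok & n_depth < cfg$min_depth, "normal_depth")
  reasons <- add(reasons, ok & v$t_alt < cfg$min_tumor_alt, "tumor_alt")
  reasons <- add(reasons, ok & v$n_alt > cfg$max_normal_alt, "normal_alt")
  bl <- rep(FALSE, nrow(v))
  bl[ok] <- in_blacklist(v$chrom[ok], v$pos[ok], cfg$blacklist)
  reasons <- add(reasons, bl, "blacklist")
  passed <- lengths(reasons) == 0
  v$pass <- passed
  v$reasons <- vapply(reasons, function(r) paste(r, collapse = ","),
                      character(1))
  list(pass = v[passed, setdiff(names(v), c("pass", "reasons")),
                drop = FALSE],
       fail = v[!passed, , drop = FALSE],
       audited = v)
}

#' Detect germline variants rendered unopposed by somatic LoH
#'
#' A germline heterozygous variant (germline BAF inside
#' \code{germline_band}) is reported as unopposed when its locus lies in a
#' chromosome or segment called LoH and the tumor ALT:REF read ratio is at
#' least \code{ratio_min}. The observed ratio is additionally compared with
#' the purity-expected ratio for a one-copy loss retaining the ALT allele,
#' \eqn{1/(1-\rho)}; agreement within \code{tol} (relative) is reported as a
#' consistency flag, not enforced as a filter.
#'
#' @param germline data.frame of germline variants (chrom, pos, gene,
#'   t_ref, t_alt, n_ref, n_alt).
#' @param karyotype A \code{karyotype} object for the tumor.
#' @param purity Tumor purity in (0, 1].
#' @param ratio_min Minimum tumor ALT:REF ratio (default 1.5).
#' @param germline_band Open interval of germline BAF defining "~1:1"
#'   (default (0.4, 0.6)).
#' @param tol Relative tolerance of the purity-consistency flag
#'   (default 0.5).
#' @param segments Optional \code{cn_segments} with \code{loh}; when given,
#'   segment-level LoH (partial-chromosome events) also qualifies a locus.
#' @return data.frame of reported variants with germline_ratio, tumor_ratio,
#'   expected_ratio, purity_consistent.
#' @export
unopposed_germline <- function(germline, karyotype, purity, ratio_min = 1.5,
                               germline_band = c(0.4, 0.6), tol = 0.5,
                               segments = NULL) {
  v <- germline
  n_depth <- v$n_ref + v$n_alt
  t_depth <- v$t_ref + v$t_alt
  if (any(t_depth == 0)) {
    warning(sum(t_depth == 0), " variant(s) with zero tumor depth skipped")
  }
  g_baf <- ifelse(n_depth > 0, v$n_alt / n_depth, NA_real_)
  in_band <- !is.na(g_baf) & g_baf > germline_band[1] &
    g_baf < germline_band[2]
  chrom_loh <- karyotype$calls$loh[match(v$chrom, karyotype$calls$chrom)]
  in_loh <- chrom_loh %in% TRUE
  if (!is.null(segments)) {
    for (i in seq_len(nrow(v))) {
      hit <- segments$chrom == v$chrom[i] & v$pos[i] > segments$start &
        v$pos[i] <= segments$end & segments$loh %in% TRUE
      if (any(hit)) in_loh[i] <- TRUE
    }
  }
  tumor_ratio <- ifelse(v$t_ref > 0, v$t_alt / v$t_ref, Inf)
  germline_ratio <- ifelse(v$n_ref > 0, v$n_alt / v$n_ref, Inf)
  keep <- in_band & in_loh & t_depth > 0 & tumor_ratio >= ratio_min
  out <- v[keep, , drop = FALSE]
  out$germline_ratio <- germline_ratio[keep]
  out$tumor_ratio <- tumor_ratio[keep]
  out$expected_ratio <- rep(if (purity < 1) 1 / (1 - purity) else Inf,
                            nrow(out))
  out$purity_consistent <- is.finite(out$tumor_ratio) &
    is.finite(out$expected_ratio) &
    abs(out$tumor_ratio - out$expected_ratio) <= tol * out$expected_ratio
  rownames(out) <- NULL
  out
}

#' Call biallelic inactivation status of a gene per tumor
#'
#' \code{biallelic}: a passing somatic variant in the gene and LoH over its
#' locus (the second, wild-type allele is lost); \code{monoallelic}: variant
#' without LoH; \code{loh_only}: LoH without variant; \code{wild_type}:
#' neither.
#'
#' @param gene Gene identifier.
#' @param passing Passing somatic variants (with \code{gene} column).
#' @param karyotype A \code{karyotype} object.
#' @param genes Gene annotation data.frame (gene_id, chrom, start, end).
#' @param segments Optional segments for locus-level LoH on heterogeneous
#'   chromosomes.
#' @return One of "biallelic", "monoallelic", "loh_only", "wild_type".
#' @export
biallelic_inactivation <- function(gene, passing, karyotype, genes,
                                   segments = NULL) {
  g <- genes[genes$gene_id == gene, , drop = FALSE]
  if (!nrow(g)) stop("gene not in annotation: ", gene)
  has_variant <- any(passing$gene == gene)
  loh <- karyotype$calls$loh[match(g$chrom, karyotype$calls$chrom)] %in% TRUE
  if (!loh && !is.null(segments)) {
    mid <- (g$start + g$end) / 2
    hit <- segments$chrom == g$chrom & mid > segments$start &
      mid <= segments$end & segments$loh %in% TRUE
    loh <- any(hit)
  }
  if (has_variant && loh) "biallelic"
  else if (has_variant) "monoallelic"
  else if (loh) "loh_only"
  else "wild_type"
}

#' Coding-region mutation rate per megabase
#'
#' @param n_variants Number of passing coding variants (or a data.frame of
#'   them).
#' @param callable_bp Coding bp with sufficient (e.g. >= 50x) coverage.
#' @return Mutations per Mb.
#' @export
coding_mutation_rate <- function(n_variants, callable_bp) {
  if (is.data.frame(n_variants)) n_variants <- nrow(n_variants)
  if (callable_bp <= 0) stop("callable_bp must be > 0")
  n_variants / (callable_bp / 1e6)
}

#' Read a tumor/normal variant table from VCF or TSV
#'
#' VCF input must have AD FORMAT fields for both samples; \code{tumor} and
#' \code{normal} name the sample columns. INFO keys GENE, EFFECT and ORIGIN
#' are honoured when present. TSV input must already carry the package's
#' variant columns.
#'
#' @param path File path.
#' @param tumor,normal Sample column names for VCF input (defaults: first
#'   two columns).
#' @return data.frame with chrom, pos, ref, alt, gene, effect, t_ref, t_alt,
#'   n_ref, n_alt, origin.
#' @export
read_variants <- function(path, tumor = NULL, normal = NULL) {
  if (!grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    return(utils::read.delim(path, stringsAsFactors = FALSE))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(tumor)) tumor <- colnames(ad)[1]
  if (is.null(normal)) normal <- colnames(ad)[2]
  split_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    list(ref = vapply(parts, function(p) as.integer(p[1]), integer(1)),
         alt = vapply(parts, function(p) as.integer(p[2]), integer(1)))
  }
  tu <- split_ad(ad[, tumor])
  no <- split_ad(ad[, normal])
  info_field <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (is.null(x)) rep(NA_character_, nrow(ad)) else x
  }
  data.frame(
    chrom = vcfR::getCHROM(v), pos = vcfR::getPOS(v),
    ref = vcfR::getREF(v), alt = vcfR::getALT(v),
    gene = info_field("GENE"), effect = info_field("EFFECT"),
    t_ref = tu$ref, t_alt = tu$alt, n_ref = no$ref, n_alt = no$alt,
    origin = info_field("ORIGIN"), stringsAsFactors = FALSE
  )
}

#' Write a variant table as a minimal VCF
#'
#' Emits a VCFv4.2 file with TUMOR and NORMAL sample columns carrying GT:AD
#' and INFO keys GENE, EFFECT, ORIGIN, for interchange with standard
#' toolchains.
#'
#' @param variants Variant data.frame (package columns).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_variants_vcf <- function(variants, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Effect class\">",
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"somatic or germline\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOR", "NORMAL", sep = "\t")
  )
  body <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", ".",
          sprintf("GENE=%s;EFFECT=%s;ORIGIN=%s", v$gene, v$effect, v$origin),
          "GT:AD",
          sprintf("./.:%d,%d", v$t_ref, v$t_alt),
          sprintf("./.:%d,%d", v$n_ref, v$n_alt), sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
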