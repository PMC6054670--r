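# Tile counts -> normalized log2 ratios -> CBS segments -> integer CN.

#' Normalized tumor/normal log2 ratio per genome tile
#'
#' Pipeline: (1) library-size scaling of tumor counts to the normal total;
#' (2) raw ratio \code{log2((tumor + 0.5) / (normal + 0.5))}; (3) removal of
#' the coverage-dependent trend by robust local regression of the raw ratio
#' on log2 normal coverage (and on the optional per-tile covariate, e.g. GC
#' fraction, in a second pass); (4) recentering so the genome-wide median is
#' 0. Tiles with normal count below \code{min_normal} are masked and excluded
#' from normalization and segmentation.
#'
#' @param tumor,normal Tile count tracks (data.frames chrom, start, end,
#'   count) on the identical tiling.
#' @param loess_frac Smoother span for the local regression (default 0.3).
#' @param min_normal Normal-count floor below which a tile is masked
#'   (default 10).
#' @param covariate Optional numeric per-tile covariate.
#' @return data.frame of class \code{log_ratio_track}: chrom, start, end,
#'   normal, tumor, lr, masked.
#' @export
tile_log_ratio <- function(tumor, normal, loess_frac = 0.3, min_normal = 10,
                           covariate = NULL) {
  if (nrow(tumor) != nrow(normal) ||
      !all(tumor$chrom == normal$chrom & tumor$start == normal$start &
             tumor$end == normal$end)) {
    stop("tumor and normal tracks must share an identical tiling")
  }
  masked <- normal$count < min_normal
  if (all(masked)) stop("all tiles masked (normal coverage below floor)")
  if (sum(!masked) < 100) {
    stop("need >= 100 unmasked tiles for stable normalization")
  }
  t_scaled <- tumor$count * sum(as.numeric(normal$count)) /
    sum(as.numeric(tumor$count))
  raw <- log2((t_scaled + 0.5) / (normal$count + 0.5))
  lr <- raw
  detrend <- function(r, x, keep) {
    if (length(unique(x[keep])) < 10) return(r)  # nothing to fit against
    fit <- stats::lowess(x[keep], r[keep], f = loess_frac)
    trend <- stats::approx(fit$x, fit$y, xout = x, rule = 2, ties = mean)$y
    r - trend
  }
  lr <- detrend(lr, log2(normal$count + 0.5), !masked)
  if (!is.null(covariate)) lr <- detrend(lr, covariate, !masked)
  lr <- lr - stats::median(lr[!masked])
  out <- data.frame(chrom = tumor$chrom, start = tumor$start,
                    end = tumor$end, normal = normal$count,
                    tumor = tumor$count, lr = lr, masked = masked,
                    stringsAsFactors = FALSE)
  class(out) <- c("log_ratio_track", class(out))
  out
}

#' Mask tiles overlapping a blacklist
#'
#' @param track A \code{log_ratio_track}.
#' @param blacklist data.frame (chrom, start, end), 0-based half-open, e.g.
#'   from [read_bed()].
#' @return The track with overlapping tiles masked.
#' @export
apply_blacklist <- function(track, blacklist) {
  if (is.null(blacklist) || !nrow(blacklist)) return(track)
  tr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1, track$end))
  bl <- GenomicRanges::GRanges(blacklist$chrom,
                               IRanges::IRanges(blacklist$start + 1,
                                                blacklist$end))
  hit <- suppressWarnings(GenomicRanges::countOverlaps(tr, bl)) > 0
  track$masked <- track$masked | hit
  track
}

#' Read a BED file of intervals
#' @param path BED file path.
#' @return data.frame chrom, start, end (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a tile count track from BED-like TSV
#' @param path Path to a 4-column (chrom, start, end, count) tab-separated
#'   file, with or without header.
#' @return data.frame chrom, start, end, count.
#' @export
read_tile_track <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("chrom", first)
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "count")
  df[, 1:4]
}

#' Shrink isolated single-tile outliers
#'
#' A tile is treated as an outlier when it is far (beyond \code{z_cap} noise
#' SDs) from the median of its window *and* from every other value in the
#' window -- the second condition preserves genuine short segments, whose
#' tiles have same-level neighbours. The noise SD is estimated robustly from
#' first differences (MAD / sqrt(2)). Outliers are shrunk to their window
#' median; everything else is unchanged.
#'
#' @param track A \code{log_ratio_track}.
#' @param window Odd window width >= 3 (default 5).
#' @param z_cap Outlier threshold in noise SDs (default 3).
#' @return The track with \code{lr} smoothed.
#' @export
smooth_outliers <- function(track, window = 5, z_cap = 3) {
  stopifnot(window >= 3, window %% 2 == 1)
  half <- (window - 1) / 2
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch & !track$masked)
    x <- track$lr[idx]
    m <- length(x)
    if (m < window) next
    sigma <- stats::mad(diff(x)) / sqrt(2)
    if (!is.finite(sigma)) next
    new_x <- x
    for (i in seq_len(m)) {
      lo <- max(1, i - half)
      hi <- min(m, i + half)
      others <- x[setdiff(lo:hi, i)]
      med <- stats::median(x[lo:hi])
      if (min(abs(x[i] - others)) > z_cap * sigma &&
          abs(x[i] - med) > z_cap * sigma) {
        new_x[i] <- med
      }
    }
    track$lr[idx] <- new_x
  }
  track
}

# Recursive CBS on one numeric vector; returns sorted breakpoint boundaries
# (0-based, excluding 0 and m).
cbs_breakpoints <- function(x, alpha, n_perm, min_width) {
  m <- length(x)
  if (m < 2 * min_width) return(integer(0))
  res <- .cbs_perm_pvalue(x, as.integer(min_width), as.integer(n_perm),
                          alpha)
  if (res$i < 0 || res$p >= alpha) return(integer(0))
  cuts <- setdiff(c(res$i, res$j), c(0L, m))
  if (!length(cuts)) return(integer(0))
  bounds <- c(0L, sort(as.integer(cuts)), m)
  out <- sort(as.integer(cuts))
  for (k in seq_len(length(bounds) - 1)) {
    lo <- bounds[k]
    hi <- bounds[k + 1]
    sub <- cbs_breakpoints(x[(lo + 1):hi], alpha, n_perm, min_width)
    out <- c(out, lo + sub)
  }
  sort(unique(out))
}

#' Segment a log-ratio track by circular binary segmentation
#'
#' Recursively finds the arc maximizing the two-sample t-statistic between
#' in-arc and out-of-arc tiles, accepts the split when its permutation
#' p-value (label permutations with early stopping) is below \code{alpha}
#' and every resulting part has at least \code{min_width} tiles, then
#' recurses into the parts. Adjacent segments whose means differ by less
#' than \code{merge_tol} are merged. Deterministic given \code{seed}.
#'
#' @param track A \code{log_ratio_track} (masked tiles are excluded).
#' @param alpha Split significance level (default 0.01).
#' @param n_perm Permutations per split test (default 1000).
#' @param min_width Minimum tiles per segment (default 3).
#' @param merge_tol Post-hoc merge threshold on adjacent segment means
#'   (default 0.05 log2 units).
#' @param seed Optional integer seed applied locally (caller RNG state is
#'   restored).
#' @return data.frame of class \code{cn_segments}: chrom, start, end (bp,
#'   0-based half-open), first_tile, last_tile (indices into the unmasked
#'   tiles of the chromosome), n_tiles, mean_lr, and placeholder columns
#'   baf_dev, n_hets, cn, loh filled by later stages.
#' @export
cbs_segment <- function(track, alpha = 0.01, n_perm = 1000, min_width = 3,
                        merge_tol = 0.05, seed = NULL) {
  run <- function() {
    segs <- list()
    for (ch in unique(track$chrom)) {
      idx <- which(track$chrom == ch & !track$masked)
      x <- track$lr[idx]
      m <- length(x)
      if (m == 0) next
      if (m < min_width) {
        warning("chromosome ", ch, " has fewer than min_width usable tiles; ",
                "returning a single segment")
        bks <- integer(0)
      } else {
        bks <- cbs_breakpoints(x, alpha, n_perm, min_width)
      }
      bounds <- c(0L, bks, m)
      means <- vapply(seq_len(length(bounds) - 1), function(k) {
        mean(x[(bounds[k] + 1):bounds[k + 1]])
      }, numeric(1))
      # merge adjacent segments with near-identical means
      keep <- TRUE
      while (length(means) > 1 && any(abs(diff(means)) < merge_tol)) {
        k <- which.min(abs(diff(means)))
        bounds <- bounds[-(k + 1)]
        means <- vapply(seq_len(length(bounds) - 1), function(j) {
          mean(x[(bounds[j] + 1):bounds[j + 1]])
        }, numeric(1))
      }
      for (k in seq_len(length(bounds) - 1)) {
        ti <- idx[(bounds[k] + 1):bounds[k + 1]]
        segs[[length(segs) + 1]] <- data.frame(
          chrom = ch, start = track$start[ti[1]],
          end = track$end[ti[length(ti)]],
          first_tile = bounds[k] + 1L, last_tile = bounds[k + 1],
          n_tiles = length(ti), mean_lr = means[k],
          baf_dev = NA_real_, n_hets = NA_integer_,
          cn = NA_integer_, loh = NA, stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, segs)
    class(out) <- c("cn_segments", class(out))
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Re-anchor segment means on the modal copy-number level
#'
#' The genome-wide median used by [tile_log_ratio()] is only an unbiased
#' zero point while aberrant tiles are rare; in heavily aneuploid genomes
#' the median drifts into the flank of the diploid cluster. This step
#' clusters segment means (single-linkage on the sorted means with gap
#' \code{tol}), takes the cluster covering the most bp as the neutral level,
#' and shifts all means so that its bp-weighted mean is zero. Assumes the
#' modal state is diploid, the standard anchoring assumption of read-depth
#' CN callers.
#'
#' @param segments A \code{cn_segments} data.frame.
#' @param tol Gap (log2 units) separating clusters of segment means
#'   (default 0.1).
#' @return Segments with \code{mean_lr} shifted; the shift is recorded in
#'   attribute \code{recenter_shift}.
#' @export
recenter_segments <- function(segments, tol = 0.1) {
  ord <- order(segments$mean_lr)
  means <- segments$mean_lr[ord]
  len <- (segments$end - segments$start)[ord]
  cluster <- cumsum(c(1, diff(means) > tol))
  bp <- tapply(len, cluster, sum)
  modal <- as.integer(names(bp)[which.max(bp)])
  shift <- sum((means * len)[cluster == modal]) /
    sum(len[cluster == modal])
  segments$mean_lr <- segments$mean_lr - shift
  attr(segments, "recenter_shift") <- shift
  segments
}

#' Assign integer copy number to segments under the purity model
#'
#' Each segment receives the integer \eqn{c \in 0..max\_cn} whose expected
#' log2 ratio \eqn{\log_2((\rho c + 2(1-\rho))/2)} is closest to the segment
#' mean; ties break toward the diploid state.
#'
#' @param segments A \code{cn_segments} data.frame.
#' @param purity Tumor purity \eqn{\rho} in (0, 1].
#' @param max_cn Largest copy number considered (default 8).
#' @return Segments with \code{cn} filled.
#' @export
assign_segment_cn <- function(segments, purity, max_cn = 8) {
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  cand <- 0:max_cn
  cand <- cand[order(abs(cand - 2))]  # which.min tie-break toward 2
  exp_lr <- expected_log_ratio(purity, cand)
  segments$cn <- vapply(segments$mean_lr, function(r) {
    cand[which.min(abs(r - exp_lr))]
  }, integer(1))
  segments
}
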