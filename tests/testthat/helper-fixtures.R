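# Shared fixtures, built lazily and cached for the session.

.cache <- new.env(parent = emptyenv())

# Nine-tumor cohort at default desk scale; enough for integration checks
# without the full study-size run.
small_cohort <- function() {
  if (is.null(.cache$small)) {
    cfg <- sim_config(n_tumors = c(group1 = 3, group2 = 3, group3 = 3),
                      seed = 42)
    .cache$small <- simulate_cohort(cfg)
  }
  .cache$small
}

# Build a log-ratio track directly from per-chromosome value vectors.
make_track <- function(..., tile_size = 3000) {
  vals <- list(...)
  if (is.null(names(vals))) names(vals) <- paste0("chr", seq_along(vals))
  df <- do.call(rbind, lapply(names(vals), function(ch) {
    x <- vals[[ch]]
    data.frame(chrom = ch,
               start = (seq_along(x) - 1L) * tile_size,
               end = seq_along(x) * tile_size,
               normal = 100L, tumor = 100L,
               lr = x, masked = FALSE, stringsAsFactors = FALSE)
  }))
  class(df) <- c("log_ratio_track", class(df))
  df
}

# Exhaustive single-change-point scan: the location b maximizing the
# two-sample t statistic between x[1..b] and x[(b+1)..m]. Oracle for CBS on
# tracks with at most one step.
single_split_oracle <- function(x, min_width = 3) {
  m <- length(x)
  best_t <- -Inf
  best_b <- NA_integer_
  for (b in min_width:(m - min_width)) {
    a <- x[1:b]
    c <- x[(b + 1):m]
    t <- abs(mean(a) - mean(c)) / sqrt(1 / b + 1 / (m - b))
    if (t > best_t) {
      best_t <- t
      best_b <- b
    }
  }
  best_b
}

# Brute-force Mann-Whitney U: pairwise win count with half-credit ties.
brute_U <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Karyotype object straight from per-chromosome CN/LoH vectors.
new_karyotype_for_test <- function(cn, loh, id = "t") {
  truth <- structure(list(
    tumor_id = id,
    chromosomes = data.frame(chrom = paste0("chr", seq_along(cn)),
                             cn = as.integer(cn), loh = loh,
                             stringsAsFactors = FALSE),
    segments = NULL, purity = 0.5, men1_somatic = FALSE, group = 3L
  ), class = "karyotype_truth")
  truth_to_karyotype(truth)
}
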