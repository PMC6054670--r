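flat_tiles <- function(n = 300, count = 100, chrom = "chr1") {
  data.frame(chrom = chrom, start = (seq_len(n) - 1L) * 3000L,
             end = seq_len(n) * 3000L, count = count,
             stringsAsFactors = FALSE)
}

test_that("log ratios are zero for identical and purely rescaled tracks", {
  withr::with_seed(7, {
    normal <- flat_tiles()
    normal$count <- stats::rpois(nrow(normal), 100)
    same <- tile_log_ratio(normal, normal)
    expect_true(all(abs(same$lr[!same$masked]) < 1e-8))
    doubled <- normal
    doubled$count <- normal$count * 2L
    scaled <- tile_log_ratio(doubled, normal)
    expect_true(all(abs(scaled$lr[!scaled$masked]) < 1e-8))
  })
})

test_that("a hemizygous chromosome lands near log2(1/2) in a pure tumor", {
  withr::with_seed(8, {
    n <- 500
    normal <- rbind(flat_tiles(n, chrom = "chr1"), flat_tiles(n, chrom = "chr2"),
                    flat_tiles(n, chrom = "chr3"))
    normal$count <- stats::rpois(nrow(normal), 200)
    tumor <- normal
    mult <- ifelse(normal$chrom == "chr2", 0.5, 1)
    tumor$count <- stats::rpois(nrow(normal), 200 * mult)
    lr <- tile_log_ratio(tumor, normal)
    segs <- recenter_segments(cbs_segment(lr, seed = 2))
    m2 <- segs$mean_lr[segs$chrom == "chr2"]
    expect_equal(length(m2), 1)
    # diploid majority anchors the modal level, so chr2 sits at log2(1/2)
    expect_lt(abs(m2 - log2(0.5)), 0.05)
    expect_lt(max(abs(segs$mean_lr[segs$chrom != "chr2"])), 0.05)
  })
})

test_that("tiling mismatch and over-masking are rejected", {
  normal <- flat_tiles()
  tumor <- flat_tiles()
  tumor$start[5] <- tumor$start[5] + 1L
  expect_error(tile_log_ratio(tumor, normal), "identical tiling")
  low <- flat_tiles(count = 2)
  expect_error(tile_log_ratio(flat_tiles(), low), "masked")
})

test_that("outlier smoothing shrinks lone spikes and keeps short segments", {
  withr::with_seed(9, {
    base <- stats::rnorm(200, sd = 0.1)
    tr <- make_track(base)
    expect_equal(smooth_outliers(tr)$lr, tr$lr)  # no outliers: unchanged
    spiked <- base
    spiked[100] <- 5
    tr_s <- make_track(spiked)
    sm <- smooth_outliers(tr_s)
    expect_lt(abs(sm$lr[100]), 0.5)
    expect_equal(sm$lr[-100], spiked[-100])
    # two adjacent shifted tiles are a candidate segment, not outliers
    pair <- base
    pair[100:101] <- pair[100:101] + 5
    kept <- smooth_outliers(make_track(pair))
    expect_equal(kept$lr[100:101], pair[100:101])
  })
})

test_that("CBS leaves i.i.d. noise unsegmented and finds a clear step", {
  withr::with_seed(10, {
    null_track <- make_track(stats::rnorm(400))
    segs <- cbs_segment(null_track, seed = 1)
    expect_equal(nrow(segs), 1)
    expect_equal(segs$n_tiles, 400)

    x <- c(stats::rnorm(500), stats::rnorm(500, mean = 3))
    segs2 <- cbs_segment(make_track(x), seed = 1)
    expect_equal(nrow(segs2), 2)
    expect_lt(abs(segs2$n_tiles[1] - 500), 2)
    expect_lt(abs(segs2$mean_lr[1]), 0.2)
    expect_gt(segs2$mean_lr[2], 2.8)
  })
})

test_that("CBS matches the exhaustive single-split oracle on short tracks", {
  hits <- 0
  reps <- 25
  withr::with_seed(12, {
    for (r in seq_len(reps)) {
      b_true <- sample(60:140, 1)
      x <- c(stats::rnorm(b_true), stats::rnorm(200 - b_true, mean = 3))
      segs <- cbs_segment(make_track(x), seed = r)
      oracle <- single_split_oracle(x)
      if (nrow(segs) == 2 && abs(segs$n_tiles[1] - oracle) <= 1) {
        hits <- hits + 1
      }
    }
  })
  expect_gte(hits / reps, 0.95)
})

test_that("CBS recovers a multi-segment intra-chromosomal profile in order", {
  withr::with_seed(13, {
    # a tumor whose chromosome carries loss, neutral and gain segments
    x <- c(stats::rnorm(300, -1, 0.3), stats::rnorm(300, 0, 0.3),
           stats::rnorm(400, 0.58, 0.3))
    segs <- cbs_segment(make_track(x), seed = 3)
    expect_equal(nrow(segs), 3)
    expect_true(all(diff(segs$mean_lr) > 0))
    segs <- assign_segment_cn(segs, purity = 1)
    expect_equal(segs$cn, c(1, 2, 3))
  })
})

test_that("segments partition the unmasked tiles exactly once", {
  withr::with_seed(14, {
    tr <- make_track(stats::rnorm(150), c(stats::rnorm(100),
                                          stats::rnorm(80, 2)))
    tr$masked[sample(nrow(tr), 20)] <- TRUE
    segs <- cbs_segment(tr, seed = 4)
    for (ch in unique(tr$chrom)) {
      n_unmasked <- sum(tr$chrom == ch & !tr$masked)
      expect_equal(sum(segs$n_tiles[segs$chrom == ch]), n_unmasked)
    }
  })
})

test_that("integer CN assignment inverts the expected log ratio", {
  segs <- data.frame(chrom = "chr1", start = 0, end = 3e6, first_tile = 1,
                     last_tile = 1000, n_tiles = 1000, mean_lr = 0,
                     baf_dev = NA_real_, n_hets = NA_integer_,
                     cn = NA_integer_, loh = NA)
  expect_equal(assign_segment_cn(segs, 0.5)$cn, 2)
  segs$mean_lr <- log2(0.75)
  expect_equal(assign_segment_cn(segs, 0.5)$cn, 1)
  segs$mean_lr <- 0.585
  expect_equal(assign_segment_cn(segs, 1)$cn, 3)
  # separation property: recovery of every integer state
  for (rho in c(0.2, 0.4, 0.7, 1)) {
    for (cc in 0:8) {
      segs$mean_lr <- expected_log_ratio(rho, cc)
      expect_equal(assign_segment_cn(segs, rho)$cn, cc)
    }
  }
})

test_that("blacklisted tiles are masked before segmentation", {
  tr <- make_track(rep(0, 100))
  bl <- data.frame(chrom = "chr1", start = 30000, end = 36000)
  masked <- apply_blacklist(tr, bl)
  expect_equal(sum(masked$masked), 2)
  expect_equal(which(masked$masked), c(11, 12))
})
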