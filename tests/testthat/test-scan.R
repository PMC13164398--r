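test_that("window means reproduce simple hand cases", {
  sites <- data.frame(chrom = "c1", pos = c(10, 50, 90),
                      value = c(1, 2, 3))
  tr <- smooth_window_mean(sites, window_size = 100, step = 100)
  expect_equal(tr$value[1], 2)
  expect_equal(tr$n_sites[1], 3)

  const <- data.frame(chrom = "c1", pos = seq(1, 1e5, by = 997), value = 7)
  trc <- smooth_window_mean(const, window_size = 1e4, step = 1e3)
  expect_true(all(trc$value[trc$n_sites > 0] == 7))
  expect_true(all(is.na(trc$value[trc$n_sites == 0])))
})

test_that("window means equal a brute-force re-mean oracle", {
  withr::with_seed(31, {
    sites <- data.frame(
      chrom = sample(c("c1", "c2"), 400, replace = TRUE),
      pos = sample.int(2e5, 400), value = rnorm(400))
    sites$value[sample(400, 30)] <- NA
  })
  w <- 2.5e4; s <- 5e3
  track <- smooth_window_mean(sites, w, s)
  for (i in sample(nrow(track), 60)) {
    row <- track[i, ]
    inw <- sites$chrom == row$chrom & sites$pos >= row$start &
      sites$pos <= row$start + w - 1 & !is.na(sites$value)
    expected <- if (any(inw)) mean(sites$value[inw]) else NA_real_
    expect_equal(row$value, expected, tolerance = 1e-12)
  }
})

test_that("tricube smoothing honors the kernel definition", {
  # isolated site keeps its own value
  expect_equal(tricube_smooth(c(100), c(5), window_size = 1000), 5)
  # neighbour exactly at the half-window distance has weight zero
  expect_equal(tricube_smooth(c(0, 500), c(5, 100), window_size = 1000),
               c(5, 100))
  # brute-force weighted mean oracle on a cluster
  withr::with_seed(32, {
    pos <- sort(sample.int(1e6, 200))
    g <- rexp(200)
  })
  w <- 2e5; d_half <- w / 2
  got <- tricube_smooth(pos, g, w)
  for (i in sample(200, 40)) {
    d <- abs(pos - pos[i])
    keep <- d <= d_half
    wt <- (1 - (d[keep] / d_half)^3)^3
    expect_equal(got[i], sum(wt * g[keep]) / sum(wt), tolerance = 1e-12)
  }
})

test_that("empirical thresholds are linear-interpolation sample quantiles", {
  tr <- data.frame(chrom = "c1", start = 1, end = 2, value = 0:999)
  expect_equal(empirical_threshold(tr, 0.999), 998.001)
  tr2 <- data.frame(value = rep(3.3, 50))
  expect_equal(empirical_threshold(tr2, 0.42), 3.3)
  tr3 <- data.frame(value = c(1, 2, 3))
  expect_equal(empirical_threshold(tr3, 0.5), 2)
  expect_error(empirical_threshold(data.frame(value = NA_real_), 0.5),
               "non-missing")
})

# A constructed one-chromosome scene: a supra-cutoff plateau of windows
# covering a variant cluster, used for the interval-calling rules.
interval_scene <- function(n_above) {
  pos <- seq(1e4, 3e5, by = 1e4)  # 30 variants
  value <- rep(0.1, 30)
  value[10:(9 + n_above)] <- 0.9  # cluster exceeding the cutoff
  sites <- data.frame(chrom = "c1", pos = pos, value = value)
  track <- smooth_window_mean(sites, window_size = 5e4, step = 1e4)
  list(sites = sites, track = track)
}

test_that("interval calling enforces the ten-variant support rule", {
  sc <- interval_scene(n_above = 12)
  iv <- call_intervals(sc$track, sc$sites, cutoff = 0.5)
  expect_equal(nrow(iv), 1)
  expect_gte(iv$n_above, 10)
  expect_true(iv$start <= 1e5 && iv$end >= 2.1e5)

  sc9 <- interval_scene(n_above = 9)
  expect_equal(nrow(call_intervals(sc9$track, sc9$sites, cutoff = 0.5)), 0)

  # all windows below the cutoff: nothing called
  expect_equal(nrow(call_intervals(sc$track, sc$sites, cutoff = 2)), 0)
})

test_that("raising the cutoff never increases the number of intervals", {
  withr::with_seed(33, {
    sites <- data.frame(chrom = "c1", pos = sort(sample.int(5e5, 300)),
                        value = abs(rnorm(300)))
  })
  track <- smooth_window_mean(sites, 5e4, 1e4)
  cuts <- quantile(track$value, c(0.5, 0.7, 0.9, 0.97, 0.999), na.rm = TRUE)
  counts <- vapply(cuts, function(ct)
    nrow(call_intervals(track, sites, ct, min_variants_above = 3)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("interval lengths reproduce the reported candidate-region sizes", {
  # ED, G', and delta-index candidate intervals on chromosome 10
  len <- interval_length(
    start = c(13202553, 11892034, 13400050),
    end = c(16561272, 17271104, 16799575))
  expect_equal(len$bp, c(3358719, 5379070, 3399525))
  expect_equal(len$mb, c(3.36, 5.38, 3.40))
  expect_equal(interval_length(5, 5 + 1e6)$mb, 1.00)
  expect_error(interval_length(10, 10), "start")
})

test_that("overlap arithmetic matches the three-channel comparison", {
  index_iv <- list(chrom = "Chr10", start = 13400050, end = 16799575)
  ed_iv <- list(chrom = "Chr10", start = 13202553, end = 16561272)
  gp_iv <- list(chrom = "Chr10", start = 11892034, end = 17271104)

  ov <- interval_overlap(index_iv, ed_iv)
  expect_equal(round(100 * ov$frac_b, 1), 94.1)  # fraction of the ED interval

  ov2 <- interval_overlap(index_iv, gp_iv)
  expect_true(ov2$a_in_b)   # delta-index interval inside the G' interval
  expect_false(ov2$b_in_a)

  disjoint <- interval_overlap(list(chrom = "c1", start = 1, end = 10),
                               list(chrom = "c1", start = 20, end = 30))
  expect_equal(disjoint$overlap_bp, 0)
  other_chrom <- interval_overlap(index_iv,
                                  list(chrom = "Chr2", start = 1, end = 10))
  expect_equal(other_chrom$overlap_bp, 0)
  expect_false(other_chrom$a_in_b)
})

test_that("the three-channel scan runs end to end on a small simulation", {
  gm <- toy_genome(n_markers = 60)
  sim <- simulate_bsa(gm, trait_model("chrA", 2.5e7), 200,
                      sim_config(bulk_size = 25), seed = 55)
  st <- compute_site_stats(filter_informative(sim$variants)$variants)
  sc <- bsa_scan(st, config = scan_config(min_variants_above = 3),
                 chrom_lengths = gm$chromosomes)
  expect_named(sc, c("delta", "gprime", "ed4"))
  for (ch in names(sc)) {
    expect_s3_class(sc[[ch]]$track, "window_track")
    expect_true(is.finite(sc[[ch]]$cutoff))
    expect_s3_class(sc[[ch]]$intervals, "candidate_intervals")
  }
})
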