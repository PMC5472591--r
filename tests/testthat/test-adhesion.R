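test_that("adhesion/cytosol ratios are mean quotients with gain invariance", {
  img <- matrix(5, 20, 20)
  adh <- matrix(FALSE, 20, 20); adh[1:5, 1:5] <- TRUE
  cyt <- matrix(FALSE, 20, 20); cyt[10:20, 10:20] <- TRUE
  expect_equal(adhesion_cytosol_ratio(img, adh, cyt), 1)

  img2 <- img; img2[adh] <- 30; img2[cyt] <- 10
  expect_equal(adhesion_cytosol_ratio(img2, adh, cyt), 3)
  # global multiplicative gain cancels; additive offset does not
  expect_equal(adhesion_cytosol_ratio(img2 * 7.5, adh, cyt), 3)
  expect_false(isTRUE(all.equal(adhesion_cytosol_ratio(img2 + 50, adh, cyt),
                                3)))
  # inverted contrast
  img3 <- img; img3[adh] <- 2; img3[cyt] <- 40
  expect_lt(adhesion_cytosol_ratio(img3, adh, cyt), 1)

  expect_error(adhesion_cytosol_ratio(img2, matrix(FALSE, 20, 20), cyt),
               "empty")
  expect_error(adhesion_cytosol_ratio(img2, adh, adh), "disjoint")
  expect_error(adhesion_cytosol_ratio(img * 0, adh, cyt), "zero")
})

test_that("vinculin/talin ratios are simple quotients of enrichment", {
  expect_equal(vinculin_talin_ratio(2, 2), 1)
  expect_equal(vinculin_talin_ratio(3, 1.5), 0.5)
  expect_error(vinculin_talin_ratio(0, 1), "positive")
  # rising talin enrichment with flat vinculin: monotone decreasing ratio
  talin <- c(1.5, 2.5, 3.5, 4.5)
  expect_true(all(diff(vinculin_talin_ratio(talin, 2)) < 0))
})

test_that("paxillin masks extend the signal and flag degenerate thresholds", {
  ch <- matrix(0, 64, 64)
  expect_warning(m0 <- build_paxillin_mask(ch, 0.3, threshold = 0.5),
                 "empty")
  expect_false(any(m0))

  ch[32, 32] <- 100
  areas <- vapply(c(0.2, 0.4, 0.8), function(sig) {
    sum(build_paxillin_mask(ch, sig, threshold = 0.05, pixel_size_um = 0.1))
  }, numeric(1))
  expect_true(all(diff(areas) > 0))          # area grows with sigma
  m <- build_paxillin_mask(ch, 0.4, threshold = 0.05, pixel_size_um = 0.1)
  expect_true(m[32, 32])                      # blob contains the puncta
  expect_gte(sum(m), sum(ch >= 0.05))         # blur extends structures

  expect_warning(full <- build_paxillin_mask(ch, 0.3, threshold = 0),
                 "full")
  expect_true(all(full))
  expect_error(build_paxillin_mask(ch, -1, threshold = 1), "positive")
})

test_that("Mander's M1 behaves as a thresholded intensity fraction", {
  a <- matrix(runif(400), 20, 20)
  mask <- matrix(TRUE, 20, 20)
  expect_equal(manders_overlap(a, a, mask, threshold_b = -1), 1)
  expect_equal(manders_overlap(a, a, mask, threshold_b = 2), 0)

  # disjoint supports
  b <- matrix(0, 20, 20); b[1:10, ] <- 1
  a2 <- matrix(0, 20, 20); a2[11:20, ] <- 1
  expect_equal(manders_overlap(a2, b, mask, 0.5), 0)

  # half the channel-a intensity on b-positive pixels
  a3 <- matrix(0, 20, 20); a3[1:10, 1] <- 1; a3[11:20, 1] <- 1
  expect_equal(manders_overlap(a3, b, mask, 0.5), 0.5)

  # invariant to uniform scaling of channel a, always within [0, 1]
  set.seed(61)
  for (rep in 1:10) {
    x <- matrix(runif(100), 10, 10)
    y <- matrix(runif(100), 10, 10)
    mk <- matrix(sample(c(TRUE, FALSE), 100, replace = TRUE), 10, 10)
    if (!any(mk)) next
    m1 <- manders_overlap(x, y, mk, 0.5)
    expect_gte(m1, 0); expect_lte(m1, 1)
    expect_equal(manders_overlap(x * 13, y, mk, 0.5), m1)
  }
  expect_warning(res <- manders_overlap(a3 * 0, b, mask, 0.5), "undefined")
  expect_true(is.na(res))
})

test_that("fibronectin fractions are area fractions summing to one", {
  pat <- make_micropattern(64, 6, 8, pixel_size_um = 1)
  adh <- matrix(FALSE, 64, 64); adh[1:6, 1:6] <- TRUE   # wholly on a square
  expect_equal(fn_fraction(adh, pat), 1)
  expect_equal(fn_fraction(adh, pat) + fn_fraction(adh, !pat), 1)

  # uniformly random adhesion pixels over a checkerboard-like lattice:
  # fraction approaches pattern coverage (law of large numbers)
  set.seed(62)
  rnd <- matrix(runif(64 * 64) < 0.5, 64, 64)
  n_px <- sum(rnd)
  frac <- fn_fraction(rnd, pat)
  cov <- mean(pat)
  expect_lt(abs(frac - cov), 3 * sqrt(cov * (1 - cov) / n_px))
  expect_warning(empty <- fn_fraction(matrix(FALSE, 64, 64), pat), "empty")
  expect_true(is.na(empty))
})

test_that("micropattern coverage follows the analytic lattice geometry", {
  expect_equal(mean(make_micropattern(64, 8, 8, pixel_size_um = 1)), 1)
  expect_equal(mean(make_micropattern(81.92, 7.68, 10.24,
                                      pixel_size_um = 0.16)), 0.5625)
  expect_equal(mean(make_micropattern(81.92, 5.12, 10.24,
                                      pixel_size_um = 0.16)), 0.25)
  # non-pixel-aligned geometry (whole periods in the field): coverage
  # within 0.5 pp of the analytic value at every tested resolution
  errs <- vapply(c(256, 512, 1024), function(n) {
    fld <- 7 * 9.7
    abs(mean(make_micropattern(fld, 6.1, 9.7, pixel_size_um = fld / n)) -
          (6.1 / 9.7)^2)
  }, numeric(1))
  expect_true(all(errs < 0.005))
  expect_error(make_micropattern(80, 12, 10), "exceed")
  expect_error(make_micropattern(-1, 5, 10), "positive")
})

test_that("adhesion segmentation recovers bright objects above the floor", {
  set.seed(63)
  truth <- matrix(FALSE, 128, 128)
  truth[30:35, 40:48] <- TRUE
  truth[80:86, 90:95] <- TRUE
  ch <- 20 + 100 * truth + matrix(rnorm(128^2, 0, 2), 128)
  seg <- segment_adhesions(ch, pixel_size_um = 0.1)
  expect_gt(sum(seg & truth) / sum(truth), 0.7)    # recovers the objects
  expect_lt(sum(seg & !truth) / sum(!truth), 0.02) # little background
  cyt <- cytosol_mask(matrix(TRUE, 128, 128), seg, pixel_size_um = 0.1)
  expect_false(any(cyt & seg))
  expect_gt(adhesion_cytosol_ratio(ch, seg, cyt), 3)
})

test_that("migration speeds summarize path length over duration", {
  still <- data.frame(track_id = 1, t_min = c(0, 30, 60), x_um = 0, y_um = 0)
  expect_equal(migration_rate(still)$per_track$path_speed_um_h, 0)

  straight <- data.frame(track_id = 1, t_min = seq(0, 60, 10),
                         x_um = seq(0, 60, 10), y_um = 0)
  res <- migration_rate(straight)
  expect_equal(res$per_track$path_speed_um_h, 60)
  expect_equal(res$per_track$net_speed_um_h, 60)

  # path speed exceeds net speed for a bent track
  bent <- data.frame(track_id = 1, t_min = c(0, 30, 60),
                     x_um = c(0, 30, 0), y_um = 0)
  rb <- migration_rate(bent)$per_track
  expect_equal(rb$path_speed_um_h, 60)
  expect_equal(rb$net_speed_um_h, 0)

  expect_error(migration_rate(data.frame(track_id = 1, t_min = c(0, 0),
                                         x_um = 0:1, y_um = 0)),
               "non-increasing")
})

test_that("cohort speed recovers the generator parameter", {
  tk <- gen_tracks(60, persistence = 0.6, n = 100, seed = 64,
                   speed_noise = 0.15)
  res <- migration_rate(tk)
  expect_equal(res$n, 100)
  expect_lt(abs(res$mean_um_h - 60) / 60, 0.05)
  # persistence 1 with no speed noise: straight line of length s * duration
  one <- gen_tracks(45, persistence = 1, duration_h = 2, n = 1, seed = 65)
  r1 <- migration_rate(one)$per_track
  expect_equal(r1$path_speed_um_h, 45, tolerance = 1e-9)
  expect_equal(r1$net_speed_um_h, 45, tolerance = 1e-9)
})

test_that("channels and masks round-trip through TIFF", {
  pat <- make_micropattern(81.92, 7.68, 10.24, pixel_size_um = 0.16)
  f <- tempfile(fileext = ".tif")
  write_channel_tiff(pat, f)
  back <- read_channel_tiff(f) > 0.5
  expect_equal(sum(back), sum(pat))
  f2 <- tempfile(fileext = ".tif")
  write_channel_tiff(matrix(runif(64^2), 64), f2)
  expect_equal(dim(read_channel_tiff(f2)), c(64, 64))
})
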