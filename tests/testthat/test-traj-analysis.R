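# Square-prism fixture: four single-atom-per-level chains at the corners of
# a `side` nm square, one water at the prism centroid, plus far waters.
prism_frame <- function(side = 0.6, n_far = 50, centre_water = TRUE) {
  ranges <- r3_helix_ranges()
  corners <- list(H1 = c(0, 0), H2 = c(side, 0),
                  H3 = c(side, side), H4 = c(0, side))
  prot <- do.call(rbind, lapply(names(ranges), function(h) {
    res <- seq(ranges[[h]][1], ranges[[h]][2])
    data.frame(resno = res, resid = "ALA", elety = "CA",
               x = corners[[h]][1], y = corners[[h]][2],
               z = seq(0, 2, length.out = length(res)))
  }))
  waters <- NULL
  if (centre_water) waters <- rbind(waters, c(side / 2, side / 2, 1))
  if (n_far > 0) {
    waters <- rbind(waters,
                    cbind(runif(n_far, 5, 8), runif(n_far, 5, 8),
                          runif(n_far, 0, 2)))
  }
  solvated_frame(0, prot, if (is.null(waters)) matrix(numeric(0), 0, 3)
                 else waters)
}

test_that("core-water counting matches the brute-force oracle on fixtures", {
  empty <- prism_frame(n_far = 0, centre_water = FALSE)
  expect_identical(count_penetrating_waters(empty), 0L)

  set.seed(31)
  fr <- prism_frame(side = 1.2)
  # centroid-to-corner distance is 0.85 nm: counted at 0.9 nm, not at 0.5
  expect_equal(count_penetrating_waters(fr, cutoff_nm = 0.9), 1)
  expect_equal(count_penetrating_waters(fr, cutoff_nm = 0.9),
               oracle_core_count(fr, r3_helix_ranges(), 0.9))
  expect_equal(count_penetrating_waters(fr, cutoff_nm = 0.5), 0)

  # rigid-motion invariance
  moved <- random_rigid_motion(fr)
  expect_equal(count_penetrating_waters(moved, cutoff_nm = 0.9), 1)

  # water-permutation invariance and +1 on adding a qualifying water
  small <- prism_frame(side = 0.6)
  perm <- small
  perm$water_oxygens <- perm$water_oxygens[sample(nrow(perm$water_oxygens)), ]
  expect_equal(count_penetrating_waters(small), count_penetrating_waters(perm))
  plus <- small
  plus$water_oxygens <- rbind(plus$water_oxygens, c(0.3, 0.3, 0.5))
  expect_equal(count_penetrating_waters(plus),
               count_penetrating_waters(small) + 1L)
})

test_that("fast counter equals the all-pairs oracle on random configurations", {
  set.seed(32)
  for (rep in 1:40) {
    fr <- random_frame(n_waters = sample(20:300, 1),
                       atoms_per_helix = sample(5:24, 1))
    cutoff <- runif(1, 0.3, 1.5)
    expect_identical(count_penetrating_waters(fr, cutoff_nm = cutoff),
                     oracle_core_count(fr, r3_helix_ranges(), cutoff))
  }
})

test_that("counts are monotone non-decreasing in the cutoff", {
  set.seed(33)
  for (rep in 1:10) {
    fr <- random_frame(n_waters = 150, atoms_per_helix = 10)
    cuts <- sort(runif(4, 0.2, 2))
    counts <- vapply(cuts, function(cc)
      count_penetrating_waters(fr, cutoff_nm = cc), integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("counting rejects empty helices and bad cutoffs", {
  fr <- prism_frame()
  expect_error(count_penetrating_waters(fr, cutoff_nm = 0), "positive")
  gutted <- fr
  gutted$protein_atoms <-
    gutted$protein_atoms[gutted$protein_atoms$resno > 820, ]
  expect_error(count_penetrating_waters(gutted), "H1")
})

test_that("sliding averages honour both window conventions", {
  expect_equal(sliding_average(rep(4, 12)), rep(4, 12))
  expect_equal(sliding_average(c(0, 10), 2, align = "trailing"), c(0, 5))
  expect_equal(sliding_average(c(0, 10), 2, align = "centered"), c(5, 5))
  x <- c(3, 1, 4, 1, 5)
  expect_equal(sliding_average(x, 1), x)
  expect_error(sliding_average(x, 0), "window")
  expect_identical(sliding_average(numeric(0)), numeric(0))
  # trailing window 3 by hand
  expect_equal(sliding_average(x, 3, align = "trailing"),
               c(3, 2, 8 / 3, 2, 10 / 3))
})

test_that("sliding averages stay within the input range", {
  set.seed(34)
  for (rep in 1:10) {
    x <- rnorm(sample(5:50, 1))
    for (al in c("trailing", "centered")) {
      s <- sliding_average(x, sample(1:10, 1), align = al)
      expect_true(all(s >= min(x) - 1e-12 & s <= max(x) + 1e-12))
    }
  }
})

test_that("penetration series recover generator schedules frame by frame", {
  tr <- gen_bundle_trajectory(20, 0, 3, seed = 41)
  ps <- penetration_series(tr)
  expect_equal(ps$count, rep(3L, 20))
  expect_equal(ps$smoothed, rep(3, 20))

  # one extra core water per frame: strictly increasing, oracle-checked
  tr2 <- gen_bundle_trajectory(8, 0, function(t) as.integer(round(t)) + 1L,
                               seed = 42, duration_ns = 7)
  ps2 <- penetration_series(tr2)
  expect_equal(ps2$count, 1:8)
  for (i in seq_along(tr2)) {
    expect_equal(ps2$count[i],
                 oracle_core_count(tr2[[i]], r3_helix_ranges(), 0.5))
  }

  # replicate mean of identical series is the series
  avg <- average_replicates(list(ps, ps, ps, ps, ps))
  expect_equal(avg$count, as.numeric(ps$count))

  # interpolation path: shifted grid, constant series
  shifted <- ps; shifted$time_ns <- shifted$time_ns + 0.05
  avg2 <- average_replicates(list(ps, shifted))
  expect_true(all(abs(avg2$count - 3) < 1e-12))
})

test_that("displacement series report per-frame anchor distances in nm", {
  tr <- gen_bundle_trajectory(5, 0, 0, seed = 43)
  ds <- displacement_series(tr)
  expect_named(ds, c("time_ns", "d1", "d2", "d3", "d4"))
  for (d in c("d1", "d2", "d3", "d4")) {
    expect_true(all(abs(ds[[d]] - ds[[d]][1]) < 1e-12))  # static trajectory
    expect_true(all(ds[[d]] >= 0))
  }

  # translation invariance
  fr <- tr[[1]]
  fr2 <- fr
  fr2$protein_atoms[, c("x", "y", "z")] <-
    fr2$protein_atoms[, c("x", "y", "z")] + 1
  fr2$time_ns <- 1
  both <- displacement_series(list(fr, fr2))
  expect_equal(both$d3[1], both$d3[2], tolerance = 1e-12)

  # direct Euclidean check: 808 and 896 placed 2.5 nm apart
  toy <- data.frame(resno = c(800L, 804L, 808L, 815L,
                              888L, 896L, 900L, 904L),
                    resid = "ALA", elety = "CA",
                    x = c(0, 0, 0, 0, 0, 2.5, 0, 0),
                    y = 0, z = 0)
  dtoy <- displacement_series(list(solvated_frame(0, toy,
                                                  matrix(numeric(0), 0, 3))))
  expect_equal(dtoy$d3, 2.5)

  # distances match direct recomputation and are symmetric in the pair
  ds_swap <- displacement_series(tr, anchor_pairs = list(d3 = c(896L, 808L)))
  expect_equal(ds_swap$d3, ds$d3)

  # missing anchor names frame and residue
  broken <- tr
  broken[[3]]$protein_atoms <-
    broken[[3]]$protein_atoms[broken[[3]]$protein_atoms$resno != 904, ]
  expect_error(displacement_series(broken), "frame 3.*904")
})

test_that("open-rate trajectories grow d3 at the requested rate", {
  tr <- gen_bundle_trajectory(11, 0.1, 0, seed = 44, duration_ns = 10)
  ds <- displacement_series(tr)
  expect_equal(ds$d3[11] - ds$d3[1], 1.0, tolerance = 1e-9)
  expect_true(all(diff(ds$d3) > 0))
})

test_that("refolding time uses the stays-in-band criterion", {
  baseline <- 0.85
  times <- seq(0, 10, by = 0.5)
  # already folded throughout
  expect_equal(refold_time(times, rep(baseline, length(times)), baseline), 0)
  # decay entering the band exactly at t = 7 ns and staying
  d3 <- ifelse(times < 7, baseline + 0.05 + 0.5 * (7 - times) / 7, baseline)
  expect_equal(refold_time(times, d3, baseline, tol_nm = 0.05), 7)
  # transient touch then exit: not counted as refolded
  d3b <- rep(baseline + 1, length(times))
  d3b[5] <- baseline
  expect_true(is.na(refold_time(times, d3b, baseline)))
  expect_error(refold_time(times, d3, baseline = -1), "positive")
})

test_that("frame tables round-trip through CSV", {
  tr <- gen_bundle_trajectory(3, 0, 2, seed = 45, n_background_waters = 5)
  f <- tempfile(fileext = ".csv")
  write_frame_table(tr, f)
  back <- read_frame_table(f)
  expect_length(back, 3)
  expect_equal(back[[2]]$time_ns, tr[[2]]$time_ns)
  expect_equal(back[[2]]$water_oxygens, unname(tr[[2]]$water_oxygens),
               ignore_attr = TRUE)
  expect_equal(penetration_series(back)$count,
               penetration_series(tr)$count)

  mf <- tempfile(fileext = ".csv")
  write_metric_csv(penetration_series(tr), mf)
  long <- read.csv(mf)
  expect_setequal(unique(long$metric), c("count", "smoothed"))
})
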