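#' Synthetic solvated four-helix-bundle trajectory
#'
#' Builds an idealized bundle that opens under load: four straight
#' dummy-atom chains (one heavy atom per residue) at the corners of a
#' square prism, residue-numbered to contain every pull/displacement anchor
#' (adjacent chains run antiparallel, so the four H1-H4 anchor pairs sit at
#' matched heights and d3 equals the H1-H4 separation exactly). The H1-H4
#' separation grows at `open_rate_nm_per_ns`; at each frame exactly
#' `n_core_waters(t)` water oxygens are placed so they satisfy the
#' core-penetration criterion, plus far-field background waters that never
#' do. Every frame is verified against an all-pairs distance check before
#' emission. The analysis operators consume only coordinates, so this
#' geometric fidelity -- not physical realism -- is what the generator
#' provides.
#'
#' @param n_frames Number of frames (>= 2).
#' @param open_rate_nm_per_ns Growth rate of the H1-H4 separation (nm/ns).
#' @param n_core_waters Integer, or function of time (ns) returning the
#'   core-water count per frame.
#' @param seed RNG seed (fixes output bit-for-bit).
#' @param duration_ns Trajectory length (default 10 ns, the pulling-run
#'   length).
#' @param side_nm Initial square side / H1-H4 separation (default 0.6 nm,
#'   small enough that centre waters lie within the 0.5 nm criterion of all
#'   four chains).
#' @param cutoff_nm Penetration cutoff the placement is validated against.
#' @param n_background_waters Far-field waters per frame (default 50).
#' @return List of [solvated_frame()]s with attribute `ground_truth`.
#' @export
gen_bundle_trajectory <- function(n_frames, open_rate_nm_per_ns = 0,
                                  n_core_waters = 0, seed = NULL,
                                  duration_ns = 10, side_nm = 0.6,
                                  cutoff_nm = 0.5,
                                  n_background_waters = 50L) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (!is.null(seed)) withr::local_seed(seed)
  core_n <- if (is.function(n_core_waters)) n_core_waters else {
    force(n_core_waters); function(t) n_core_waters
  }
  times <- seq(0, duration_ns, length.out = n_frames)
  ranges <- r3_helix_ranges()

  helix_atoms <- function(w_sep) {
    # corner (x,y) positions; H3 and H4 move with the opening separation
    xy <- list(H1 = c(0, 0), H2 = c(side_nm, 0),
               H3 = c(side_nm, w_sep), H4 = c(0, w_sep))
    z_of <- list(
      H1 = function(r) (r - 796) * 0.15,
      H2 = function(r) (r - 824) * 0.12,
      H3 = function(r) (880 - r) * 0.125,
      H4 = function(r) (904 - r) * 0.15 + 0.6)
    do.call(rbind, lapply(names(ranges), function(h) {
      res <- seq(ranges[[h]][1], ranges[[h]][2])
      data.frame(resno = res, resid = "ALA", elety = "CA",
                 x = xy[[h]][1], y = xy[[h]][2], z = z_of[[h]](res))
    }))
  }

  schedule <- vapply(times, function(t) as.integer(core_n(t)), integer(1))
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    t <- times[i]
    w_sep <- side_nm + open_rate_nm_per_ns * t
    prot <- helix_atoms(w_sep)
    k <- schedule[i]
    # feasibility: a centre water must reach all four corner chains
    centre <- c(side_nm / 2, w_sep / 2)
    reach <- sqrt(max(centre[1], side_nm - centre[1])^2 +
                    max(centre[2], w_sep - centre[2])^2)
    # worst case: xy jitter adds radially, atom spacing (<= 0.15 nm) puts
    # the nearest chain atom up to 0.075 nm away in z
    worst <- sqrt((reach + 0.02 * sqrt(2))^2 + 0.075^2)
    if (k > 0 && worst > cutoff_nm) {
      stop("core too open at t = ", t,
           " ns to place penetrating waters within the ", cutoff_nm,
           " nm criterion")
    }
    core <- if (k > 0) {
      cbind(centre[1] + stats::runif(k, -0.02, 0.02),
            centre[2] + stats::runif(k, -0.02, 0.02),
            stats::runif(k, 0.8, 2.2))
    } else matrix(numeric(0), 0, 3)
    bg <- if (n_background_waters > 0) {
      r <- stats::runif(n_background_waters, 4, 6)
      th <- stats::runif(n_background_waters, 0, 2 * pi)
      cbind(centre[1] + r * cos(th), centre[2] + r * sin(th),
            stats::runif(n_background_waters, -1, 4))
    } else matrix(numeric(0), 0, 3)
    fr <- solvated_frame(t, prot, rbind(core, bg))
    got <- allpairs_core_count(fr, ranges, cutoff_nm)
    if (got != k) {
      stop("internal placement check failed at frame ", i, ": placed ", k,
           " core waters but the all-pairs criterion finds ", got)
    }
    frames[[i]] <- fr
  }
  structure(frames,
            ground_truth = list(kind = "bundle_traj", times_ns = times,
                                open_rate_nm_per_ns = open_rate_nm_per_ns,
                                n_core_waters = schedule,
                                side_nm = side_nm, cutoff_nm = cutoff_nm,
                                duration_ns = duration_ns, seed = seed))
}

# Plain all-pairs core-water criterion used to validate generator output.
allpairs_core_count <- function(frame, helix_ranges, cutoff_nm) {
  W <- frame$water_oxygens
  if (nrow(W) == 0) return(0L)
  n_ok <- 0L
  for (i in seq_len(nrow(W))) {
    w <- W[i, ]
    ok <- TRUE
    for (h in c("H1", "H2", "H3", "H4")) {
      rng <- helix_ranges[[h]]
      sel <- frame$protein_atoms$resno >= rng[1] &
        frame$protein_atoms$resno <= rng[2]
      A <- as.matrix(frame$protein_atoms[sel, c("x", "y", "z")])
      d <- sqrt(rowSums(sweep(A, 2, w)^2))
      if (min(d) > cutoff_nm) { ok <- FALSE; break }
    }
    if (ok) n_ok <- n_ok + 1L
  }
  n_ok
}

#' Synthetic FRAP record with known mobile fraction and half-time
#'
#' Constructs bleach-ROI and whole-cell traces such that the double-ratio
#' normalization recovers `F(t) = M (1 - exp(-k t))` exactly at zero noise:
#' the raw post-bleach ROI trace is `floor + (1 - floor) * F(t)` relative
#' to its pre-bleach level, and a shared exponential acquisition-fading
#' factor multiplies both channels (the double ratio cancels it
#' algebraically).
#'
#' @param mobile_fraction Ground-truth plateau M.
#' @param half_time_s Ground-truth half-recovery time (s); `k = ln2 / t1/2`.
#' @param noise_sigma Multiplicative Gaussian noise SD on both channels.
#' @param fading_rate Acquisition fading rate (1/s) applied to both
#'   channels.
#' @param seed RNG seed.
#' @param dt_s Sampling interval (default 0.5 s).
#' @param pre_s,post_s Pre-/post-bleach durations (defaults 5 s and 90 s).
#' @param bleach_floor Raw post-bleach floor as a fraction of the
#'   pre-bleach level (default 0.3).
#' @param b0,cell0 Pre-bleach mean intensities of ROI and whole cell.
#' @return A [frap_record()] with attribute `ground_truth`.
#' @export
gen_frap <- function(mobile_fraction, half_time_s, noise_sigma = 0,
                     fading_rate = 0, seed = NULL, dt_s = 0.5,
                     pre_s = 5, post_s = 90, bleach_floor = 0.3,
                     b0 = 1000, cell0 = 2000) {
  stopifnot(mobile_fraction >= 0, half_time_s > 0,
            bleach_floor >= 0, bleach_floor < 1)
  if (!is.null(seed)) withr::local_seed(seed)
  times <- seq(-pre_s, post_s, by = dt_s)
  bi <- which(times >= 0)[1]
  k <- log(2) / half_time_s
  tpost <- pmax(times, 0)
  F_model <- ifelse(times < 0, 1,
                    bleach_floor +
                      (1 - bleach_floor) * mobile_fraction *
                        (1 - exp(-k * tpost)))
  fading <- exp(-fading_rate * (times - times[1]))
  noise <- function(n) 1 + stats::rnorm(n, 0, noise_sigma)
  B <- pmax(b0 * F_model * fading * noise(length(times)), 0)
  Cell <- pmax(cell0 * fading * noise(length(times)), 0)
  rec <- frap_record(times, B, Cell, bleach_index = bi)
  attr(rec, "ground_truth") <- list(kind = "frap",
                                    mobile_fraction = mobile_fraction,
                                    half_time_s = half_time_s, rate_k = k,
                                    noise_sigma = noise_sigma,
                                    fading_rate = fading_rate,
                                    bleach_floor = bleach_floor, seed = seed)
  rec
}

#' Synthetic micropatterned adhesion scene with known fibronectin fraction
#'
#' Generates a square-lattice fibronectin pattern at the requested coverage
#' and places elliptical adhesions so the ground-truth adhesion AREA
#' fraction on fibronectin equals `fn_adhesion_fraction` up to
#' discretization: each adhesion is placed wholly on or wholly off the
#' pattern squares, joining the class that moves the running area fraction
#' towards the target, so the realized fraction ends within one adhesion
#' footprint of it. The
#' paxillin channel mirrors the adhesions plus noise; the talin channel is
#' adhesion enrichment over a cytosolic background.
#'
#' @param pattern_coverage Fibronectin area coverage of the lattice
#'   (default 0.5625, i.e. square/pitch = 0.75 -- the 56 % layout).
#' @param fn_adhesion_fraction Target fraction of adhesion area on
#'   fibronectin.
#' @param n_adhesions Number of adhesions (default 500).
#' @param seed RNG seed.
#' @param size_px Raster side (default 512).
#' @param pixel_size_um Pixel size (default 0.16 um).
#' @param pitch_um Lattice pitch (default 10.24 um = 64 px).
#' @param talin_enrichment Adhesion/cytosol talin enrichment factor.
#' @return An `adhesion_scene` list: `channels` (talin, paxillin, pattern),
#'   `masks` (pattern, adhesion), `pixel_size_um`, `ground_truth`.
#' @export
gen_scene <- function(pattern_coverage = 0.5625, fn_adhesion_fraction,
                      n_adhesions = 500L, seed = NULL, size_px = 512L,
                      pixel_size_um = 0.16, pitch_um = 10.24,
                      talin_enrichment = 4) {
  stopifnot(fn_adhesion_fraction >= 0, fn_adhesion_fraction <= 1,
            pattern_coverage > 0, pattern_coverage <= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  field_um <- size_px * pixel_size_um
  square_um <- sqrt(pattern_coverage) * pitch_um
  pattern <- make_micropattern(field_um, square_um, pitch_um, pixel_size_um)

  adh <- matrix(FALSE, size_px, size_px)
  # greedy area balancing: each adhesion goes to the class that moves the
  # realized AREA fraction towards the target, so the final fraction is
  # within one adhesion footprint of it (count-stratified assignment would
  # leave percentage-point-scale sampling error from size variance)
  area_on <- 0; area_off <- 0
  for (i in seq_len(n_adhesions)) {
    on_target <- if (fn_adhesion_fraction >= 1) TRUE
      else if (fn_adhesion_fraction <= 0) FALSE
      else if (area_on + area_off == 0) TRUE
      else area_on / (area_on + area_off) < fn_adhesion_fraction
    placed <- FALSE
    for (try in seq_len(2000)) {
      a <- stats::runif(1, 2, 5)            # semi-axes in px
      b <- stats::runif(1, 1.5, a)
      th <- stats::runif(1, 0, pi)
      r <- ceiling(a)
      cx <- sample(seq(r + 1L, size_px - r), 1)
      cy <- sample(seq(r + 1L, size_px - r), 1)
      off <- expand.grid(dx = -r:r, dy = -r:r)
      u <- (off$dx * cos(th) + off$dy * sin(th)) / a
      v <- (-off$dx * sin(th) + off$dy * cos(th)) / b
      inside <- u^2 + v^2 <= 1
      px <- cbind(cx + off$dx[inside], cy + off$dy[inside])
      onpat <- pattern[px]
      if ((on_target && all(onpat)) || (!on_target && !any(onpat))) {
        new_px <- sum(!adh[px])
        adh[px] <- TRUE
        if (on_target) area_on <- area_on + new_px else
          area_off <- area_off + new_px
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place adhesion ", i,
                      " (pattern geometry too tight for the ellipse sizes)")
  }

  realized <- sum(adh & pattern) / sum(adh)
  noise <- function() matrix(stats::rnorm(size_px^2, 0, 3), size_px)
  channels <- list(
    talin = pmax(30 * (1 + (talin_enrichment - 1) * adh) + noise(), 0),
    paxillin = pmax(20 + 100 * adh + noise(), 0),
    pattern = pmax(10 + 70 * pattern + noise(), 0))
  structure(list(channels = channels,
                 masks = list(pattern = pattern, adhesion = adh),
                 pixel_size_um = pixel_size_um,
                 ground_truth = list(kind = "scene",
                                     pattern_coverage = pattern_coverage,
                                     pattern_coverage_realized =
                                       mean(pattern),
                                     fn_adhesion_fraction =
                                       fn_adhesion_fraction,
                                     fn_adhesion_fraction_realized = realized,
                                     n_adhesions = n_adhesions,
                                     seed = seed)),
            class = "adhesion_scene")
}

#' Synthetic two-state melt curve with known Tm
#'
#' @param tm_C Ground-truth melting temperature (Celsius).
#' @param dH_kJ Van 't Hoff enthalpy (default 200 kJ/mol).
#' @param baselines Named vector `bf`, `mf`, `bu`, `mu` (defaults: flat
#'   baselines at -15 and -4, the sign convention of 220 nm ellipticity).
#' @param noise_sigma Additive Gaussian noise SD (signal units).
#' @param seed RNG seed.
#' @param temp_C Temperature grid (default 20-90 C in 2 C steps).
#' @return A [melt_curve()] with attribute `ground_truth`.
#' @export
gen_melt <- function(tm_C, dH_kJ = 200,
                     baselines = c(bf = -15, mf = 0, bu = -4, mu = 0),
                     noise_sigma = 0, seed = NULL,
                     temp_C = seq(20, 90, by = 2)) {
  if (!is.null(seed)) withr::local_seed(seed)
  y <- two_state_signal(temp_C, tm_C, dH_kJ, baselines[["bf"]],
                        baselines[["mf"]], baselines[["bu"]],
                        baselines[["mu"]])
  if (noise_sigma > 0) y <- y + stats::rnorm(length(y), 0, noise_sigma)
  cv <- melt_curve(temp_C, y)
  attr(cv, "ground_truth") <- list(kind = "melt", tm_C = tm_C,
                                   dH_kJ = dH_kJ,
                                   baselines = as.list(baselines),
                                   noise_sigma = noise_sigma, seed = seed)
  cv
}

#' Synthetic persistent-random-walk migration tracks
#'
#' Constant nominal speed with optional multiplicative step-speed noise;
#' heading evolves by Gaussian turns with SD `(1 - persistence) * pi`, so
#' `persistence = 1` gives straight lines.
#'
#' @param speed_um_h Ground-truth path speed (um/h).
#' @param persistence Directional persistence in \[0, 1\].
#' @param duration_h Track duration (default 12 h).
#' @param dt_min Sampling interval (default 2 min).
#' @param n Number of tracks.
#' @param seed RNG seed.
#' @param speed_noise Multiplicative lognormal step-speed noise SD
#'   (default 0; the realized mean step speed stays `speed_um_h`).
#' @return Data frame `track_id`, `t_min`, `x_um`, `y_um` with attribute
#'   `ground_truth`.
#' @export
gen_tracks <- function(speed_um_h, persistence = 0.7, duration_h = 12,
                       dt_min = 2, n = 100L, seed = NULL, speed_noise = 0) {
  stopifnot(persistence >= 0, persistence <= 1, speed_um_h >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  t_min <- seq(0, duration_h * 60, by = dt_min)
  nstep <- length(t_min) - 1L
  step0 <- speed_um_h * dt_min / 60
  out <- do.call(rbind, lapply(seq_len(n), function(id) {
    turns <- stats::rnorm(nstep, 0, (1 - persistence) * pi)
    heading <- stats::runif(1, 0, 2 * pi) + cumsum(c(0, turns[-nstep]))
    lens <- if (speed_noise > 0) {
      step0 * exp(stats::rnorm(nstep, -speed_noise^2 / 2, speed_noise))
    } else rep(step0, nstep)
    data.frame(track_id = id, t_min = t_min,
               x_um = cumsum(c(0, lens * cos(heading))),
               y_um = cumsum(c(0, lens * sin(heading))))
  }))
  structure(out, ground_truth = list(kind = "tracks",
                                     speed_um_h = speed_um_h,
                                     persistence = persistence,
                                     duration_h = duration_h,
                                     dt_min = dt_min, n = n,
                                     speed_noise = speed_noise, seed = seed))
}

#' Write a generator's ground-truth sidecar as JSON
#'
#' @param x Any object produced by a `gen_*` function.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(x, path) {
  gt <- attr(x, "ground_truth")
  if (is.null(gt) && is.list(x)) gt <- x$ground_truth
  if (is.null(gt)) stop("object carries no ground-truth metadata")
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
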