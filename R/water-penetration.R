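#' One solvated trajectory frame
#'
#' @param time_ns Frame timestamp in ns (>= 0).
#' @param protein_atoms Data frame of protein heavy atoms: `resno`, `elety`,
#'   `x`, `y`, `z` (nm).
#' @param water_oxygens Numeric matrix (n x 3) of water oxygen coordinates
#'   (nm); may have zero rows.
#' @return An object of class `solvated_frame`.
#' @export
solvated_frame <- function(time_ns, protein_atoms, water_oxygens) {
  stopifnot(is.numeric(time_ns), length(time_ns) == 1, time_ns >= 0)
  stopifnot(is.data.frame(protein_atoms),
            all(c("resno", "elety", "x", "y", "z") %in% names(protein_atoms)))
  water_oxygens <- as.matrix(water_oxygens)
  if (length(water_oxygens) == 0) {
    water_oxygens <- matrix(numeric(0), 0, 3)
  }
  if (ncol(water_oxygens) != 3) stop("water_oxygens must be an n x 3 matrix")
  if (!all(is.finite(as.matrix(protein_atoms[, c("x", "y", "z")]))) ||
      !all(is.finite(water_oxygens))) {
    stop("all coordinates must be finite")
  }
  structure(list(time_ns = time_ns, protein_atoms = protein_atoms,
                 water_oxygens = water_oxygens),
            class = "solvated_frame")
}

#' Count water molecules penetrating the hydrophobic core
#'
#' A water oxygen counts as penetrating when its minimum distance to the
#' heavy atoms of EVERY one of the four helices is at or below the cutoff
#' (5 angstrom = 0.5 nm by default). The conjunction over helices is what
#' isolates core water; waters at the open ends of the bundle that still
#' satisfy the criterion are included. Water hydrogens and protein
#' hydrogens are never considered (the frame carries heavy atoms and water
#' oxygens only).
#'
#' The counter prunes waters outside the cutoff-expanded bounding box of
#' each helix before computing exact distances, so it scales to solvated
#' boxes; it is exact, not approximate.
#'
#' @param frame A [solvated_frame()].
#' @param helix_ranges Helix residue ranges ([r3_helix_ranges()] default).
#' @param cutoff_nm Distance cutoff in nm (> 0).
#' @return Integer count.
#' @export
count_penetrating_waters <- function(frame, helix_ranges = r3_helix_ranges(),
                                     cutoff_nm = 0.5) {
  if (!is.numeric(cutoff_nm) || length(cutoff_nm) != 1 || cutoff_nm <= 0) {
    stop("cutoff_nm must be a single positive number")
  }
  W <- frame$water_oxygens
  m <- nrow(W)
  if (m == 0) return(0L)
  ok <- rep(TRUE, m)
  cut2 <- cutoff_nm^2
  for (h in c("H1", "H2", "H3", "H4")) {
    rng <- helix_ranges[[h]]
    sel <- frame$protein_atoms$resno >= rng[1] &
      frame$protein_atoms$resno <= rng[2]
    if (!any(sel)) stop("helix ", h, " has no heavy atoms in this frame")
    A <- as.matrix(frame$protein_atoms[sel, c("x", "y", "z")])
    cand <- which(ok)
    if (length(cand) == 0) break
    # bounding-box pruning: waters outside the expanded helix box cannot
    # be within cutoff of any helix atom
    lo <- apply(A, 2, min) - cutoff_nm
    hi <- apply(A, 2, max) + cutoff_nm
    inbox <- W[cand, 1] >= lo[1] & W[cand, 1] <= hi[1] &
      W[cand, 2] >= lo[2] & W[cand, 2] <= hi[2] &
      W[cand, 3] >= lo[3] & W[cand, 3] <= hi[3]
    ok[cand[!inbox]] <- FALSE
    cand <- cand[inbox]
    if (length(cand) == 0) next
    Wc <- W[cand, , drop = FALSE]
    d2 <- outer(rowSums(Wc^2), rowSums(A^2), `+`) - 2 * Wc %*% t(A)
    ok[cand] <- apply(d2, 1, min) <= cut2 + 1e-12
  }
  sum(ok)
}

#' Sliding average of a numeric series
#'
#' The 10-frame sliding average used to smooth penetrating-water counts.
#' `align = "trailing"` (default) averages the last `min(i, window)` values
#' at position i; `align = "centered"` uses a full-length window clamped to
#' the array bounds (so the end elements share the first/last full window).
#'
#' @param values Numeric vector.
#' @param window Window length (>= 1).
#' @param align `"trailing"` or `"centered"`.
#' @return Numeric vector, same length as `values`.
#' @export
sliding_average <- function(values, window = 10L,
                            align = c("trailing", "centered")) {
  align <- match.arg(align)
  if (!is.numeric(window) || length(window) != 1 || window < 1) {
    stop("window must be a single integer >= 1")
  }
  window <- as.integer(window)
  n <- length(values)
  if (n == 0) return(numeric(0))
  if (window == 1) return(as.numeric(values))
  out <- numeric(n)
  if (align == "trailing") {
    cs <- cumsum(values)
    for (i in seq_len(n)) {
      j <- max(1L, i - window + 1L)
      out[i] <- (cs[i] - if (j > 1) cs[j - 1] else 0) / (i - j + 1L)
    }
  } else {
    w <- min(window, n)
    for (i in seq_len(n)) {
      start <- min(max(1L, i - (w - 1L) %/% 2L), n - w + 1L)
      out[i] <- mean(values[start:(start + w - 1L)])
    }
  }
  out
}

#' Penetrating-water count series over a trajectory
#'
#' @param traj List of [solvated_frame()]s (>= 1).
#' @param helix_ranges,cutoff_nm Passed to [count_penetrating_waters()].
#' @param window,align Passed to [sliding_average()].
#' @return A `water_penetration_series`: data frame `time_ns`, `count`,
#'   `smoothed`.
#' @export
penetration_series <- function(traj, helix_ranges = r3_helix_ranges(),
                               cutoff_nm = 0.5, window = 10L,
                               align = "trailing") {
  if (length(traj) < 1) stop("trajectory must contain at least one frame")
  counts <- integer(length(traj))
  times <- numeric(length(traj))
  for (i in seq_along(traj)) {
    counts[i] <- tryCatch(
      count_penetrating_waters(traj[[i]], helix_ranges, cutoff_nm),
      error = function(e) stop("frame ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    times[i] <- traj[[i]]$time_ns
  }
  structure(data.frame(time_ns = times, count = counts,
                       smoothed = sliding_average(counts, window, align)),
            class = c("water_penetration_series", "data.frame"))
}

#' Average replicate metric series onto a common time grid
#'
#' Element-wise mean across replicate runs (e.g. the 5 pulling replicates
#' behind a mean penetrating-water trace). Identical time grids are
#' averaged directly; otherwise every series is linearly interpolated onto
#' the first replicate's grid restricted to the overlap of all ranges.
#'
#' @param series_list List of data frames each holding a time column and a
#'   value column.
#' @param time_col,value_col Column names.
#' @return Data frame with the common grid and the replicate mean.
#' @export
average_replicates <- function(series_list, time_col = "time_ns",
                               value_col = "count") {
  stopifnot(length(series_list) >= 1)
  grids <- lapply(series_list, function(s) s[[time_col]])
  same <- all(vapply(grids, function(g)
    length(g) == length(grids[[1]]) && all(g == grids[[1]]), logical(1)))
  if (same) {
    grid <- grids[[1]]
    vals <- sapply(series_list, function(s) s[[value_col]])
  } else {
    lo <- max(vapply(grids, min, numeric(1)))
    hi <- min(vapply(grids, max, numeric(1)))
    if (lo > hi) stop("replicate time ranges do not overlap")
    grid <- grids[[1]][grids[[1]] >= lo & grids[[1]] <= hi]
    vals <- sapply(series_list, function(s)
      stats::approx(s[[time_col]], s[[value_col]], xout = grid)$y)
  }
  out <- data.frame(grid, rowMeans(as.matrix(vals)))
  names(out) <- c(time_col, value_col)
  out
}
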