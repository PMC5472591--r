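# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's internal code paths: the water
# oracle is a naive per-water scan with no pruning, and the conservation
# oracle is a literal per-column tally.

# Naive core-water count: for every water, minimum distance to the heavy
# atoms of each of the four helices, conjunction over helices.
oracle_core_count <- function(frame, helix_ranges, cutoff_nm) {
  W <- frame$water_oxygens
  if (nrow(W) == 0) return(0L)
  at <- frame$protein_atoms
  helix_xyz <- lapply(helix_ranges, function(rng) {
    as.matrix(at[at$resno >= rng[1] & at$resno <= rng[2],
                 c("x", "y", "z")])
  })
  count <- 0L
  for (i in seq_len(nrow(W))) {
    w <- W[i, ]
    ok <- TRUE
    for (A in helix_xyz) {
      d <- sqrt((A[, 1] - w[1])^2 + (A[, 2] - w[2])^2 + (A[, 3] - w[3])^2)
      if (min(d) > cutoff_nm) { ok <- FALSE; break }
    }
    if (ok) count <- count + 1L
  }
  count
}

# Literal per-column modal-residue tally.
oracle_conservation <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col != "-" & col != "."]
    if (length(col) == 0) return(0)
    max(table(col)) / length(col)
  }, numeric(1))
}

# Random solvated frame with four helices at arbitrary positions.
random_frame <- function(n_waters = 200, atoms_per_helix = 40,
                         box_nm = 4) {
  ranges <- r3_helix_ranges()
  prot <- do.call(rbind, lapply(names(ranges), function(h) {
    rng <- ranges[[h]]
    res <- seq(rng[1], rng[2])
    k <- min(atoms_per_helix, length(res))
    res <- res[seq_len(k)]
    origin <- runif(3, 0, box_nm)
    data.frame(resno = res, resid = "ALA", elety = "CA",
               x = origin[1] + rnorm(k, 0, 0.3),
               y = origin[2] + rnorm(k, 0, 0.3),
               z = origin[3] + seq(0, 1.5, length.out = k))
  }))
  waters <- matrix(runif(3 * n_waters, -1, box_nm + 1), ncol = 3)
  solvated_frame(0, prot, waters)
}

# Random rigid motion (rotation + translation) applied to a frame.
random_rigid_motion <- function(frame) {
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                 0, sin(th[1]), cos(th[1])), 3, byrow = TRUE)
  Ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0,
                 -sin(th[2]), 0, cos(th[2])), 3, byrow = TRUE)
  Rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0,
                 0, 0, 1), 3, byrow = TRUE)
  R <- Rx %*% Ry %*% Rz
  tr <- runif(3, -5, 5)
  P <- as.matrix(frame$protein_atoms[, c("x", "y", "z")]) %*% t(R)
  frame$protein_atoms[, c("x", "y", "z")] <- sweep(P, 2, tr, `+`)
  if (nrow(frame$water_oxygens) > 0) {
    frame$water_oxygens <- sweep(frame$water_oxygens %*% t(R), 2, tr, `+`)
  }
  frame
}

# A clean square-prism test bundle taken from the synthetic generator's
# first frame (contains every anchor alpha-carbon).
make_test_bundle <- function() {
  tr <- gen_bundle_trajectory(2, 0, 0, seed = 99, n_background_waters = 0)
  helix_bundle(tr[[1]]$protein_atoms)
}
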