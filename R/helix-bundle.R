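#' Default helix boundaries of the talin-1 R3 four-helix bundle
#'
#' Residue ranges (mouse talin-1 numbering, fragment 795-911) for the four
#' amphipathic helices of the R3 subdomain. The published anchor residues
#' (800, 804, 808, 815 in H1; 888, 896, 900, 904 in H4) and the four
#' destabilizing core positions (805, 812, 890, 897) all fall inside these
#' ranges; the exact helix termini are not fixed by experiment, so the
#' ranges are configurable wherever they are consumed.
#'
#' @return Named list with elements `H1`..`H4`, each `c(first, last)`
#'   (inclusive).
#' @export
#' @examples
#' r3_helix_ranges()
r3_helix_ranges <- function() {
  list(H1 = c(796L, 815L), H2 = c(824L, 849L),
       H3 = c(856L, 880L), H4 = c(886L, 909L))
}

# Anchor alpha-carbons of the constant-force pull geometry.
r3_fixed_anchors  <- function() c(800L, 804L, 808L, 815L)  # H1, held fixed
r3_pulled_anchors <- function() c(888L, 896L, 900L, 904L)  # H4, pulled

#' Construct a four-helix bundle model
#'
#' A `helix_bundle` is a residue-indexed atom table plus the helix ranges it
#' is interpreted under. Coordinates are in nanometres throughout.
#'
#' @param atoms Data frame with columns `resno` (integer residue number,
#'   author numbering), `resid` (3-letter residue name), `elety` (atom name,
#'   e.g. `"CA"`), and `x`, `y`, `z` (nm).
#' @param helix_ranges Named list `H1`..`H4` of inclusive residue ranges;
#'   defaults to [r3_helix_ranges()].
#' @return An object of class `helix_bundle`.
#' @export
helix_bundle <- function(atoms, helix_ranges = r3_helix_ranges()) {
  stopifnot(is.data.frame(atoms))
  needed <- c("resno", "elety", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(atoms$resid)) atoms$resid <- "ALA"
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("all atom coordinates must be finite")
  }
  validate_helix_ranges(helix_ranges)
  structure(list(atoms = atoms, helix_ranges = helix_ranges),
            class = "helix_bundle")
}

validate_helix_ranges <- function(helix_ranges) {
  if (!setequal(names(helix_ranges), c("H1", "H2", "H3", "H4"))) {
    stop("helix_ranges must be a named list with elements H1, H2, H3, H4")
  }
  rng <- lapply(helix_ranges[c("H1", "H2", "H3", "H4")], as.integer)
  for (h in names(rng)) {
    if (length(rng[[h]]) != 2 || rng[[h]][1] > rng[[h]][2]) {
      stop("helix range ", h, " must be c(first, last) with first <= last")
    }
  }
  # disjoint and ascending H1 < H2 < H3 < H4
  for (i in 1:3) {
    if (rng[[i]][2] >= rng[[i + 1]][1]) {
      stop("helix ranges must be disjoint and ascending (",
           names(rng)[i], " overlaps or follows ", names(rng)[i + 1], ")")
    }
  }
  inside <- function(r, range) r >= range[1] & r <= range[2]
  if (!all(inside(r3_fixed_anchors(), rng$H1))) {
    stop("H1 range must contain anchor residues 800, 804, 808, 815")
  }
  if (!all(inside(r3_pulled_anchors(), rng$H4))) {
    stop("H4 range must contain anchor residues 888, 896, 900, 904")
  }
  invisible(rng)
}

#' @export
print.helix_bundle <- function(x, ...) {
  cat("<helix_bundle> ", nrow(x$atoms), " atoms, residues ",
      min(x$atoms$resno), "-", max(x$atoms$resno), "\n", sep = "")
  for (h in names(x$helix_ranges)) {
    cat("  ", h, ": ", x$helix_ranges[[h]][1], "-",
        x$helix_ranges[[h]][2], "\n", sep = "")
  }
  invisible(x)
}

# Alpha-carbon coordinates for one residue; error names the residue.
ca_xyz <- function(bundle, resno) {
  a <- bundle$atoms
  hit <- a$resno == resno & a$elety == "CA"
  if (!any(hit)) stop("no alpha-carbon found for residue ", resno)
  as.numeric(a[which(hit)[1], c("x", "y", "z")])
}

bundle_coords <- function(bundle) {
  as.matrix(bundle$atoms[, c("x", "y", "z")])
}

`bundle_coords<-` <- function(bundle, value) {
  bundle$atoms[, c("x", "y", "z")] <- value
  bundle
}

#' Rigidly orient a bundle so a residue-residue vector lies along +z
#'
#' Applies the minimal rotation taking the alpha-carbon vector `a -> b` onto
#' the +z axis (the pull axis of the constant-force simulations; the default
#' pair 808/896 is the d3 vector between V808 CA and G896 CA). The motion is
#' rigid: all pairwise distances are preserved.
#'
#' @param bundle A [helix_bundle()].
#' @param a,b Residue numbers whose alpha-carbon difference defines the axis.
#' @param center Optional length-3 numeric: after rotation the bundle
#'   centroid is translated to this point (e.g. the simulation-box centre).
#'   `NULL` keeps the centroid fixed.
#' @return The transformed `helix_bundle`.
#' @export
orient_to_axis <- function(bundle, a = 808L, b = 896L, center = NULL) {
  pa <- ca_xyz(bundle, a)
  pb <- ca_xyz(bundle, b)
  v <- pb - pa
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("residues ", a, " and ", b,
                       " have coincident alpha-carbons; axis undefined")
  u <- v / nv
  z <- c(0, 0, 1)
  R <- rotation_onto(u, z)
  X <- bundle_coords(bundle)
  cen <- colMeans(X)
  Xr <- sweep(X, 2, cen) %*% t(R)
  Xr <- sweep(Xr, 2, if (is.null(center)) cen else as.numeric(center), `+`)
  bundle_coords(bundle) <- Xr
  bundle
}

# Minimal rotation matrix taking unit vector u onto unit vector w
# (Rodrigues). Handles the parallel and antiparallel degeneracies.
rotation_onto <- function(u, w) {
  cthet <- sum(u * w)
  if (cthet > 1 - 1e-14) return(diag(3))
  if (cthet < -1 + 1e-14) {
    # 180 degrees about any axis perpendicular to u
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * u) * u
    ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  ax <- c(u[2] * w[3] - u[3] * w[2],
          u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  s <- sqrt(sum(ax^2))
  ax <- ax / s
  K <- matrix(c(0, -ax[3], ax[2],
                ax[3], 0, -ax[1],
                -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - cthet) * (K %*% K)
}

#' Read a bundle from a PDB file
#'
#' Thin wrapper over [bio3d::read.pdb()]; PDB angstroms are converted to nm.
#' Only heavy protein atoms are kept.
#'
#' @param path PDB file path.
#' @param helix_ranges Helix ranges, defaults to [r3_helix_ranges()].
#' @return A [helix_bundle()].
#' @export
read_bundle_pdb <- function(path, helix_ranges = r3_helix_ranges()) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM") & !grepl("^H", at$elety), , drop = FALSE]
  helix_bundle(data.frame(resno = as.integer(at$resno), resid = at$resid,
                          elety = at$elety,
                          x = at$x / 10, y = at$y / 10, z = at$z / 10),
               helix_ranges = helix_ranges)
}

#' Read a bundle from a GROMACS .gro coordinate file
#'
#' Fixed-column parser for the gro format (coordinates already in nm).
#' Water residues (SOL/HOH/WAT/TIP3) are excluded; hydrogens are dropped.
#'
#' @inheritParams read_bundle_pdb
#' @return A [helix_bundle()].
#' @export
read_bundle_gro <- function(path, helix_ranges = r3_helix_ranges()) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  rows <- lines[3:(2 + n)]
  resno <- as.integer(substr(rows, 1, 5))
  resid <- trimws(substr(rows, 6, 10))
  elety <- trimws(substr(rows, 11, 15))
  x <- as.numeric(substr(rows, 21, 28))
  y <- as.numeric(substr(rows, 29, 36))
  z <- as.numeric(substr(rows, 37, 44))
  keep <- !(resid %in% c("SOL", "HOH", "WAT", "TIP3")) & !grepl("^H", elety)
  helix_bundle(data.frame(resno = resno, resid = resid, elety = elety,
                          x = x, y = y, z = z)[keep, , drop = FALSE],
               helix_ranges = helix_ranges)
}
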