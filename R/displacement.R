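#' The four H1-H4 displacement vectors of the R3 bundle
#'
#' Alpha-carbon pairs tracking helix separation during pulling:
#' d1 Gln800-Ala904, d2 Thr804-Ala900, d3 Val808-Gly896, d4 Ser815-Gln888.
#'
#' @return Named list of residue-number pairs.
#' @export
r3_displacement_vectors <- function() {
  list(d1 = c(800L, 904L), d2 = c(804L, 900L),
       d3 = c(808L, 896L), d4 = c(815L, 888L))
}

#' H1-H4 displacement distance series over a trajectory
#'
#' Per-frame Euclidean alpha-carbon distances (nm) for the four
#' displacement vectors (or any custom residue pairs).
#'
#' @param traj List of [solvated_frame()]s, or of [helix_bundle()]s paired
#'   with a `times_ns` vector.
#' @param anchor_pairs Named list of residue-number pairs
#'   ([r3_displacement_vectors()] default).
#' @param times_ns Frame times; taken from the frames when they are
#'   `solvated_frame`s.
#' @return A `displacement_series` data frame: `time_ns` plus one distance
#'   column per vector id.
#' @export
displacement_series <- function(traj, anchor_pairs = r3_displacement_vectors(),
                                times_ns = NULL) {
  stopifnot(length(traj) >= 1)
  if (is.null(times_ns)) {
    times_ns <- vapply(traj, function(f) {
      if (inherits(f, "solvated_frame")) f$time_ns else NA_real_
    }, numeric(1))
    if (anyNA(times_ns)) stop("times_ns must be given when frames carry no timestamps")
  }
  atom_table <- function(f) if (inherits(f, "solvated_frame")) f$protein_atoms else f$atoms
  out <- data.frame(time_ns = times_ns)
  for (id in names(anchor_pairs)) out[[id]] <- NA_real_
  for (i in seq_along(traj)) {
    at <- atom_table(traj[[i]])
    for (id in names(anchor_pairs)) {
      pr <- anchor_pairs[[id]]
      p <- lapply(pr, function(r) {
        hit <- at$resno == r & at$elety == "CA"
        if (!any(hit)) stop("frame ", i, ": no alpha-carbon for residue ", r,
                            call. = FALSE)
        as.numeric(at[which(hit)[1], c("x", "y", "z")])
      })
      out[[id]][i] <- sqrt(sum((p[[1]] - p[[2]])^2))
    }
  }
  structure(out, class = c("displacement_series", "data.frame"))
}

#' Refolding time from a relaxation-phase d3 series
#'
#' Earliest time t* after which the Val808-Gly896 distance stays within
#' `tol_nm` of its pre-stretch baseline for the remainder of the series
#' ("stays in band", not first touch, so transient crossings do not count
#' as refolding). Returns `NA` when the series ends outside the band.
#'
#' @param times_ns Time points (ns).
#' @param d3_nm d3 distances (nm), same length.
#' @param baseline_nm Equilibrated d3 distance (> 0).
#' @param tol_nm Band half-width in nm (default 0.05).
#' @return t* in ns, or `NA_real_` if not refolded.
#' @export
refold_time <- function(times_ns, d3_nm, baseline_nm, tol_nm = 0.05) {
  stopifnot(length(times_ns) == length(d3_nm), length(times_ns) >= 1)
  if (!is.numeric(baseline_nm) || baseline_nm <= 0) {
    stop("baseline_nm must be positive")
  }
  if (!is.numeric(tol_nm) || tol_nm <= 0) stop("tol_nm must be positive")
  inband <- abs(d3_nm - baseline_nm) <= tol_nm
  if (!inband[length(inband)]) return(NA_real_)
  bad <- which(!inband)
  if (length(bad) == 0) return(times_ns[1])
  times_ns[max(bad) + 1L]
}
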