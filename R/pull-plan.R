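#' Construct a constant-force pull plan for the R3 bundle
#'
#' Encodes the steered-MD pulling geometry: the alpha-carbons of H1 residues
#' 800, 804, 808 and 815 are held fixed while the alpha-carbons of H4
#' residues 888, 896, 900 and 904 are pulled at constant force along +z,
#' after orienting the bundle so the 808 -> 896 alpha-carbon vector (d3) is
#' parallel to the z axis. The default box is the 10 x 10 x 30 nm
#' rectangular solvent box used for such runs; running the MD engine itself
#' is out of scope -- the plan is a declarative description.
#'
#' @param bundle A [helix_bundle()] containing alpha-carbons for all eight
#'   anchor residues.
#' @param force_pN Constant force magnitude in piconewtons (150 pN in the
#'   reference protocol; 0 describes an equilibration run).
#' @param box_nm Length-3 box dimensions in nm.
#' @return A `pull_plan` list: `fixed_atoms`, `pulled_atoms` (data frames of
#'   `resno`, `elety`), `force_pN`, `force_direction` (unit 3-vector),
#'   `box_nm`, `orientation_vector` (`c(808, 896)`), and `bundle` -- the
#'   input bundle rigidly oriented with d3 along +z and its centroid at the
#'   box centre.
#' @export
build_pull_plan <- function(bundle, force_pN, box_nm = c(10, 10, 30)) {
  if (!is.numeric(force_pN) || length(force_pN) != 1 || force_pN < 0) {
    stop("force_pN must be a single non-negative number")
  }
  anchors <- c(r3_fixed_anchors(), r3_pulled_anchors())
  have_ca <- vapply(anchors, function(r) {
    any(bundle$atoms$resno == r & bundle$atoms$elety == "CA")
  }, logical(1))
  if (!all(have_ca)) {
    stop("bundle is missing alpha-carbon(s) for anchor residue(s): ",
         paste(anchors[!have_ca], collapse = ", "))
  }
  oriented <- orient_to_axis(bundle, 808L, 896L, center = box_nm / 2)
  structure(list(
    fixed_atoms  = data.frame(resno = r3_fixed_anchors(),  elety = "CA"),
    pulled_atoms = data.frame(resno = r3_pulled_anchors(), elety = "CA"),
    force_pN = force_pN,
    force_direction = c(0, 0, 1),
    box_nm = as.numeric(box_nm),
    orientation_vector = c(808L, 896L),
    bundle = oriented
  ), class = "pull_plan")
}

#' @export
print.pull_plan <- function(x, ...) {
  cat("<pull_plan> ", x$force_pN, " pN along (",
      paste(format(x$force_direction), collapse = ", "), ")\n", sep = "")
  cat("  fixed CA (H1):  ", paste(x$fixed_atoms$resno, collapse = ", "), "\n")
  cat("  pulled CA (H4): ", paste(x$pulled_atoms$resno, collapse = ", "), "\n")
  cat("  box:", paste(x$box_nm, collapse = " x "), "nm\n")
  invisible(x)
}

#' Write a pull plan to a flat key-value file
#'
#' Emits a plain-text description of the pulling geometry and, optionally,
#' a GROMACS-style index-group listing of the fixed and pulled
#' alpha-carbons (group names `fixed_H1` and `pulled_H4`).
#'
#' @param plan A [build_pull_plan()] result.
#' @param path Output file path.
#' @param index_groups Also append the index-group listing.
#' @return `path`, invisibly.
#' @export
write_pull_plan <- function(plan, path, index_groups = TRUE) {
  lines <- c(
    paste0("fixed_atoms_CA = ", paste(plan$fixed_atoms$resno, collapse = " ")),
    paste0("pulled_atoms_CA = ", paste(plan$pulled_atoms$resno, collapse = " ")),
    paste0("force_pN = ", format(plan$force_pN)),
    paste0("force_direction = ",
           paste(format(plan$force_direction), collapse = " ")),
    paste0("box_nm = ", paste(format(plan$box_nm), collapse = " ")),
    paste0("orientation_vector = ",
           paste(plan$orientation_vector, collapse = " "))
  )
  if (index_groups) {
    lines <- c(lines, "", "[ fixed_H1 ]",
               paste(plan$fixed_atoms$resno, collapse = " "),
               "[ pulled_H4 ]",
               paste(plan$pulled_atoms$resno, collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}
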