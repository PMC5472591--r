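#' Read a trajectory from a plain CSV frame table
#'
#' The frame-table format is a tidy CSV with columns `time_ns`, `record`
#' (`"protein"` or `"water"`), `resno`, `elety`, `x`, `y`, `z` (nm). Water
#' rows carry the oxygen position; `resno`/`elety` may be blank for water.
#' This text format is the fixture-friendly counterpart of binary
#' trajectory formats.
#'
#' @param path CSV path.
#' @return List of [solvated_frame()]s ordered by time.
#' @export
read_frame_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time_ns", "record", "x", "y", "z")
  if (!all(needed %in% names(df))) {
    stop("frame table must have columns: ", paste(needed, collapse = ", "))
  }
  lapply(sort(unique(df$time_ns)), function(t0) {
    sub <- df[df$time_ns == t0, , drop = FALSE]
    prot <- sub[sub$record == "protein", , drop = FALSE]
    wat <- sub[sub$record == "water", , drop = FALSE]
    solvated_frame(t0,
                   data.frame(resno = as.integer(prot$resno),
                              elety = as.character(prot$elety),
                              x = prot$x, y = prot$y, z = prot$z),
                   as.matrix(wat[, c("x", "y", "z")]))
  })
}

#' Write a trajectory as a CSV frame table
#'
#' @param traj List of [solvated_frame()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frame_table <- function(traj, path) {
  rows <- lapply(traj, function(f) {
    prot <- data.frame(time_ns = f$time_ns, record = "protein",
                       resno = f$protein_atoms$resno,
                       elety = f$protein_atoms$elety,
                       x = f$protein_atoms$x, y = f$protein_atoms$y,
                       z = f$protein_atoms$z)
    if (nrow(f$water_oxygens) > 0) {
      wat <- data.frame(time_ns = f$time_ns, record = "water",
                        resno = NA_integer_, elety = "OW",
                        x = f$water_oxygens[, 1], y = f$water_oxygens[, 2],
                        z = f$water_oxygens[, 3])
      rbind(prot, wat)
    } else prot
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write per-frame metrics as tidy CSV
#'
#' Long format `time_ns, metric, value, replicate`, suitable for both
#' penetration and displacement series.
#'
#' @param series A `water_penetration_series` or `displacement_series`.
#' @param path Output CSV path.
#' @param replicate Replicate label stored in the `replicate` column.
#' @return `path`, invisibly.
#' @export
write_metric_csv <- function(series, path, replicate = 1L) {
  metric_cols <- setdiff(names(series), "time_ns")
  long <- do.call(rbind, lapply(metric_cols, function(mc) {
    data.frame(time_ns = series$time_ns, metric = mc,
               value = series[[mc]], replicate = replicate)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
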