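#' Migration speeds from cell tracks
#'
#' Per-track path speed (summed step lengths over total duration, the
#' track-length-style quantification) and net speed (start-to-end
#' displacement over duration), plus the cohort mean and SD of the path
#' speed. Zero-duration tracks are dropped with a warning.
#'
#' @param tracks Data frame with columns `track_id`, `t_min`, `x_um`,
#'   `y_um`; per-track times must be strictly increasing with >= 2 points.
#' @return List: `per_track` (data frame `track_id`, `path_speed_um_h`,
#'   `net_speed_um_h`, `duration_h`), `mean_um_h`, `sd_um_h`, `n`.
#' @export
migration_rate <- function(tracks) {
  stopifnot(is.data.frame(tracks),
            all(c("track_id", "t_min", "x_um", "y_um") %in% names(tracks)))
  per <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$t_min), , drop = FALSE]
    if (nrow(tr) < 2) stop("track ", tr$track_id[1], " has fewer than 2 points")
    if (any(diff(tr$t_min) <= 0)) {
      stop("track ", tr$track_id[1], " has non-increasing time points")
    }
    dur_h <- (max(tr$t_min) - min(tr$t_min)) / 60
    if (dur_h <= 0) return(NULL)
    steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
    net <- sqrt((tr$x_um[nrow(tr)] - tr$x_um[1])^2 +
                  (tr$y_um[nrow(tr)] - tr$y_um[1])^2)
    data.frame(track_id = tr$track_id[1], path_speed_um_h = sum(steps) / dur_h,
               net_speed_um_h = net / dur_h, duration_h = dur_h)
  })
  dropped <- vapply(per, is.null, logical(1))
  if (any(dropped)) warning(sum(dropped), " zero-duration track(s) dropped")
  per_track <- do.call(rbind, per[!dropped])
  rownames(per_track) <- NULL
  list(per_track = per_track,
       mean_um_h = mean(per_track$path_speed_um_h),
       sd_um_h = stats::sd(per_track$path_speed_um_h),
       n = nrow(per_track))
}
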