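#' A raw FRAP intensity record
#'
#' Mean-intensity time series of the bleached region and the whole cell,
#' typically sampled at 0.5 s intervals for 5 s before and 90 s after
#' photobleaching.
#'
#' @param times_s Acquisition times in seconds.
#' @param bleach_roi Mean intensity of the bleach region, B(t) (>= 0).
#' @param whole_cell Mean intensity of the whole cell, Cell(t) (>= 0).
#' @param bleach_index Index of the first post-bleach frame; inferred from
#'   the largest single-frame drop in `bleach_roi` when `NULL`.
#' @return An object of class `frap_record`.
#' @export
frap_record <- function(times_s, bleach_roi, whole_cell, bleach_index = NULL) {
  n <- length(times_s)
  stopifnot(length(bleach_roi) == n, length(whole_cell) == n)
  if (any(bleach_roi < 0) || any(whole_cell < 0)) {
    stop("intensities must be non-negative")
  }
  if (is.null(bleach_index)) {
    bleach_index <- which.min(diff(bleach_roi)) + 1L
  }
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 1 || bleach_index > n) {
    stop("bleach_index ", bleach_index, " is outside 1..", n)
  }
  if (bleach_index < 3) stop("need at least 2 pre-bleach frames")
  if (n - bleach_index + 1 < 10) stop("need at least 10 post-bleach frames")
  structure(list(times_s = times_s, bleach_roi = bleach_roi,
                 whole_cell = whole_cell, bleach_index = bleach_index),
            class = "frap_record")
}

#' Double-ratio FRAP normalization
#'
#' Computes `F = [B(t)/B(t<0)] / [Cell(t)/Cell(t<0)]`, where the pre-bleach
#' references are the means of all pre-bleach frames. Dividing by the
#' whole-cell ratio cancels acquisition fading. The curve is then
#' zero-normalized: `rescale = "fullscale"` (default) maps the first
#' post-bleach value to 0 and the pre-bleach level to 1, so the fitted
#' plateau reads directly as the mobile fraction; `rescale = "subtract"`
#' only subtracts the first post-bleach value.
#'
#' @param rec A [frap_record()].
#' @param rescale `"fullscale"` or `"subtract"`.
#' @return A `frap_curve`: data frame `time_s`, `t_post_s` (time from
#'   bleach), `F`, with attributes `bleach_index` and `rescale`.
#' @export
normalize_frap <- function(rec, rescale = c("fullscale", "subtract")) {
  rescale <- match.arg(rescale)
  stopifnot(inherits(rec, "frap_record"))
  bi <- rec$bleach_index
  pre <- seq_len(bi - 1L)
  B_pre <- mean(rec$bleach_roi[pre])
  C_pre <- mean(rec$whole_cell[pre])
  if (B_pre <= 0 || C_pre <= 0) {
    stop("pre-bleach mean intensity must be positive in both channels")
  }
  if (any(rec$whole_cell <= 0)) stop("whole-cell intensity hits zero; cannot form double ratio")
  F_raw <- (rec$bleach_roi / B_pre) / (rec$whole_cell / C_pre)
  F0 <- F_raw[bi]
  Fpre <- mean(F_raw[pre])
  Fn <- if (rescale == "fullscale") {
    if (abs(Fpre - F0) < 1e-12) stop("degenerate record: no bleach depth")
    (F_raw - F0) / (Fpre - F0)
  } else {
    F_raw - F0
  }
  structure(data.frame(time_s = rec$times_s,
                       t_post_s = rec$times_s - rec$times_s[bi],
                       F = Fn),
            bleach_index = bi, rescale = rescale,
            class = c("frap_curve", "data.frame"))
}

#' Fit a single-exponential recovery to a normalized FRAP curve
#'
#' Least-squares fit of `F(t) = M * (1 - exp(-k t))` on the post-bleach
#' times (t measured from the bleach frame). The mobile fraction is the
#' fitted plateau M; the half-recovery time is `ln 2 / k`. Initialization:
#' M0 = mean of the last decile of F, k0 = ln2 / (time to half of M0);
#' bounds M in [0, 1.5], k > 0. Non-convergence or a boundary-stuck rate is
#' flagged, never silent.
#'
#' @param curve A [normalize_frap()] result (or data frame with `t_post_s`
#'   and `F`).
#' @return A `frap_fit` list: `mobile_fraction`, `rate_k` (1/s),
#'   `half_time_s`, `rms`, `converged`, `flag` (NA when clean).
#' @export
fit_frap <- function(curve) {
  post <- curve[curve$t_post_s >= 0, , drop = FALSE]
  t <- post$t_post_s
  y <- post$F
  M0 <- mean(y[t >= stats::quantile(t, 0.9)])
  if (!is.finite(M0) || M0 <= 0) M0 <- max(y, 1e-3)
  ih <- which(y >= M0 / 2)
  k0 <- if (length(ih) > 0 && t[ih[1]] > 0) log(2) / t[ih[1]] else 0.1
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ M * (1 - exp(-k * t)),
                      start = list(M = min(max(M0, 1e-3), 1.5), k = k0),
                      lower = c(M = 0, k = 1e-8),
                      upper = c(M = 1.5, k = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(mobile_fraction = NA_real_, rate_k = NA_real_,
                          half_time_s = NA_real_, rms = NA_real_,
                          converged = FALSE,
                          flag = paste("fit failed:", conditionMessage(fit))),
                     class = "frap_fit"))
  }
  cf <- stats::coef(fit)
  flag <- NA_character_
  if (cf[["k"]] <= 1e-8) flag <- "rate pinned at lower bound; recovery not resolved"
  structure(list(mobile_fraction = unname(cf[["M"]]),
                 rate_k = unname(cf[["k"]]),
                 half_time_s = log(2) / unname(cf[["k"]]),
                 rms = sqrt(mean(stats::resid(fit)^2)),
                 converged = TRUE, flag = flag),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("<frap_fit> mobile fraction = ", format(x$mobile_fraction, digits = 4),
      ", half time = ", format(x$half_time_s, digits = 4), " s",
      if (!is.na(x$flag)) paste0("  [", x$flag, "]") else "", "\n", sep = "")
  invisible(x)
}

#' Read FRAP records from CSV
#'
#' Expects columns `time_s`, `bleach_roi`, `whole_cell` and, optionally,
#' `cell_id` for multi-cell files.
#'
#' @param path CSV path.
#' @param bleach_index Passed to [frap_record()] (inferred when `NULL`).
#' @return A single [frap_record()] or a named list of them.
#' @export
read_frap_csv <- function(path, bleach_index = NULL) {
  df <- utils::read.csv(path)
  build <- function(d) frap_record(d$time_s, d$bleach_roi, d$whole_cell,
                                   bleach_index)
  if ("cell_id" %in% names(df)) {
    recs <- lapply(split(df, df$cell_id), build)
    return(recs)
  }
  build(df)
}

#' Write FRAP fit results as CSV
#'
#' @param fits Named list of `frap_fit`s (names become `cell_id`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frap_fits_csv <- function(fits, path) {
  if (inherits(fits, "frap_fit")) fits <- list(cell1 = fits)
  df <- do.call(rbind, lapply(names(fits), function(id) {
    f <- fits[[id]]
    data.frame(cell_id = id, mobile_fraction = f$mobile_fraction,
               half_time_s = f$half_time_s, k = f$rate_k, rms = f$rms,
               flag = ifelse(is.na(f$flag), "", f$flag))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
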