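#' Two-state van 't Hoff melt model
#'
#' Signal of a two-state thermal unfolding with linear folded/unfolded
#' baselines:
#' `S(T) = (b_f(T) + b_u(T) K(T)) / (1 + K(T))` with
#' `K(T) = exp[-dH/R (1/T - 1/Tm)]` (T in kelvin). At `T = Tm`, `K = 1`
#' and the unfolded fraction `K/(1+K)` is exactly 0.5.
#'
#' @param temp_C Temperatures in Celsius.
#' @param tm_C Melting temperature (Celsius).
#' @param dH_kJ Van 't Hoff enthalpy in kJ/mol.
#' @param bf,mf Folded baseline intercept and slope (per Celsius).
#' @param bu,mu Unfolded baseline intercept and slope.
#' @return Signal values.
#' @export
two_state_signal <- function(temp_C, tm_C, dH_kJ, bf, mf = 0, bu, mu = 0) {
  TK <- temp_C + 273.15
  TmK <- tm_C + 273.15
  K <- exp(-(dH_kJ * 1000 / 8.314462618) * (1 / TK - 1 / TmK))
  (bf + mf * temp_C + (bu + mu * temp_C) * K) / (1 + K)
}

#' A thermal melt curve
#'
#' @param temp_C Strictly increasing temperatures (>= 8 points; 2 degree
#'   steps are typical of single-wavelength CD melts).
#' @param signal Ellipticity or arbitrary-unit signal, same length.
#' @return Object of class `melt_curve` (data frame `temp_C`, `signal`).
#' @export
melt_curve <- function(temp_C, signal) {
  stopifnot(length(temp_C) == length(signal))
  if (length(temp_C) < 8) stop("a melt curve needs at least 8 points")
  if (any(diff(temp_C) <= 0)) stop("temperatures must be strictly increasing")
  structure(data.frame(temp_C = temp_C, signal = signal),
            class = c("melt_curve", "data.frame"))
}

#' Fit a two-state melt and recover the melting temperature
#'
#' Nonlinear least-squares fit of [two_state_signal()] to a
#' single-wavelength melt. Initialization: Tm0 at the maximum absolute
#' finite-difference slope of the signal; baselines from straight-line fits
#' to the first and last temperature quartiles; dH0 = 250 kJ/mol. Tm is
#' bounded to the scanned range. Curves without a visible transition
#' (signal span below 5x the local noise level) are flagged rather than
#' silently fitted.
#'
#' @param curve A [melt_curve()] (or data frame with `temp_C`, `signal`).
#' @return A `melt_fit` list: `tm_C`, `dH_kJ`, `baselines` (named vector
#'   bf, mf, bu, mu), `rms`, `converged`, `flag` (NA when clean).
#' @export
fit_melt <- function(curve) {
  temp <- curve$temp_C
  y <- curve$signal
  n <- length(temp)
  q1 <- seq_len(max(3L, n %/% 4L))
  q4 <- seq(n - max(3L, n %/% 4L) + 1L, n)
  lf <- stats::lm(y[q1] ~ temp[q1])
  lu <- stats::lm(y[q4] ~ temp[q4])
  noise <- stats::sd(c(stats::resid(lf), stats::resid(lu)))
  span <- abs(diff(range(y)))
  flag <- NA_character_
  if (is.finite(noise) && noise > 0 && span < 5 * noise) {
    flag <- "no clear transition: signal span below 5x baseline noise"
  }
  dy <- diff(y) / diff(temp)
  tm0 <- temp[which.max(abs(dy))]
  st <- list(bf = unname(stats::coef(lf)[1]), mf = unname(stats::coef(lf)[2]),
             bu = unname(stats::coef(lu)[1]), mu = unname(stats::coef(lu)[2]),
             dH = 250, tm = tm0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ two_state_signal(temp, tm, dH, bf, mf, bu, mu),
      start = st,
      lower = c(bf = -Inf, mf = -Inf, bu = -Inf, mu = -Inf,
                dH = 1, tm = min(temp)),
      upper = c(bf = Inf, mf = Inf, bu = Inf, mu = Inf,
                dH = 5000, tm = max(temp)),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(tm_C = NA_real_, dH_kJ = NA_real_,
                          baselines = c(bf = NA, mf = NA, bu = NA, mu = NA),
                          rms = NA_real_, converged = FALSE,
                          flag = paste("fit failed:", conditionMessage(fit))),
                     class = "melt_fit"))
  }
  cf <- stats::coef(fit)
  amp <- abs((cf[["bu"]] + cf[["mu"]] * cf[["tm"]]) -
               (cf[["bf"]] + cf[["mf"]] * cf[["tm"]]))
  if (is.na(flag) && is.finite(noise) && noise > 0 && amp < 5 * noise) {
    flag <- "no clear transition: fitted amplitude below 5x baseline noise"
  }
  if (is.na(flag) &&
      (cf[["tm"]] <= min(temp) + 1e-6 || cf[["tm"]] >= max(temp) - 1e-6)) {
    flag <- "unresolved Tm: fitted midpoint pinned at the scan boundary"
  }
  structure(list(tm_C = unname(cf[["tm"]]), dH_kJ = unname(cf[["dH"]]),
                 baselines = c(bf = unname(cf[["bf"]]), mf = unname(cf[["mf"]]),
                               bu = unname(cf[["bu"]]), mu = unname(cf[["mu"]])),
                 rms = sqrt(mean(stats::resid(fit)^2)),
                 converged = TRUE, flag = flag),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("<melt_fit> Tm = ", format(x$tm_C, digits = 4), " C, dH = ",
      format(x$dH_kJ, digits = 4), " kJ/mol",
      if (!is.na(x$flag)) paste0("  [", x$flag, "]") else "", "\n", sep = "")
  invisible(x)
}

#' Read a melt curve from CSV (`temp_C`, `signal`)
#' @param path CSV path.
#' @return A [melt_curve()].
#' @export
read_melt_csv <- function(path) {
  df <- utils::read.csv(path)
  melt_curve(df$temp_C, df$signal)
}

#' Write melt fits as CSV
#' @param fits Named list of `melt_fit`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_melt_fits_csv <- function(fits, path) {
  if (inherits(fits, "melt_fit")) fits <- list(sample1 = fits)
  df <- do.call(rbind, lapply(names(fits), function(id) {
    f <- fits[[id]]
    data.frame(sample = id, tm_C = f$tm_C, dH_kJ = f$dH_kJ, rms = f$rms,
               flag = ifelse(is.na(f$flag), "", f$flag))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
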