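#' Truncated log-parabola sensitivity function parameters
#'
#' The four-parameter model of interocular correlation sensitivity as a
#' function of spatial frequency: a parabola in log10 sensitivity over log10
#' frequency with peak gain `gamma_max` at peak frequency `f_max` and full
#' bandwidth `beta_octaves` octaves at half maximum, truncated on the
#' low-frequency side at `trunc_delta` log10 units below the peak.
#'
#' Linear sensitivity is the reciprocal of the modulation threshold
#' `M_t(f) = 10^(-S(f))`; because the modulation parameter cannot exceed 1,
#' thresholds are capped at 1 (sensitivities below 1 are floored when
#' thresholds are requested).
#'
#' @param gamma_max Peak gain, linear sensitivity units (> 1).
#' @param f_max Peak spatial frequency, cycles/degree.
#' @param beta_octaves Full bandwidth at half maximum, octaves.
#' @param trunc_delta Low-frequency truncation depth, log10 units (>= 0).
#' @return A list of class `iocsf_params` including the derived constants
#'   `kappa = log10(2)` and `beta_prime = log10(2^beta_octaves)`.
#' @examples
#' p <- iocsf_params(10, 1.5, 3, 0.5)
#' log_sensitivity(1.5, p)   # log10 of the peak gain
#' @export
iocsf_params <- function(gamma_max = 10, f_max = 1.5, beta_octaves = 3,
                         trunc_delta = 0.5) {
  stopifnot(gamma_max > 1, f_max > 0, beta_octaves > 0, trunc_delta >= 0)
  structure(list(gamma_max = gamma_max, f_max = f_max,
                 beta_octaves = beta_octaves, trunc_delta = trunc_delta,
                 kappa = log10(2),
                 beta_prime = log10(2^beta_octaves)),
            class = "iocsf_params")
}

#' @export
print.iocsf_params <- function(x, ...) {
  cat("Truncated log-parabola sensitivity function\n",
      sprintf("  peak gain      %.4g (log10 = %.4g)\n",
              x$gamma_max, log10(x$gamma_max)),
      sprintf("  peak frequency %.4g c/d\n", x$f_max),
      sprintf("  bandwidth      %.4g octaves\n", x$beta_octaves),
      sprintf("  truncation     %.4g log10 units\n", x$trunc_delta), sep = "")
  invisible(x)
}

#' Log10 sensitivity at a spatial frequency
#'
#' Evaluates the truncated log-parabola: the parabola
#' `S'(f) = log10(gamma_max) - kappa * ((log10 f - log10 f_max) /
#' (beta_prime / 2))^2`, with the low-frequency branch floored at
#' `log10(gamma_max) - trunc_delta`.
#'
#' @param f Spatial frequency, cycles/degree (vectorised, all > 0).
#' @param params An [iocsf_params()].
#' @return Log10 sensitivity, same length as `f`.
#' @export
log_sensitivity <- function(f, params) {
  if (any(f <= 0)) stop("spatial frequency must be positive")
  stopifnot(inherits(params, "iocsf_params"))
  peak <- log10(params$gamma_max)
  s <- peak - params$kappa *
    ((log10(f) - log10(params$f_max)) / (params$beta_prime / 2))^2
  floor_val <- peak - params$trunc_delta
  ifelse(f < params$f_max & s < floor_val, floor_val, s)
}

# vectorised over a parameter table (one row per parameter set), used by the
# adaptive engine; returns a length(nrow) vector for scalar f
log_sensitivity_grid <- function(f, gamma_max, f_max, beta_octaves,
                                 trunc_delta) {
  peak <- log10(gamma_max)
  bp <- log10(2^beta_octaves)
  s <- peak - log10(2) * ((log10(f) - log10(f_max)) / (bp / 2))^2
  floor_val <- peak - trunc_delta
  ifelse(f < f_max & s < floor_val, floor_val, s)
}

#' Modulation threshold at a spatial frequency
#'
#' `M_t(f) = min(10^(-S(f)), 1)`: the modulation at which the observer's
#' linear sensitivity is reached, capped at the physical maximum 1.
#'
#' @inheritParams log_sensitivity
#' @return Thresholds in `(0, 1]`.
#' @export
modulation_threshold <- function(f, params) {
  pmin(10^(-log_sensitivity(f, params)), 1)
}

#' Area under the log sensitivity function
#'
#' Trapezoidal integral of `max(S(f), 0)` over log10 frequency on an evenly
#' spaced log10 grid; the scalar summary used to track sensitivity change
#' across sessions (log10-sensitivity times log10-frequency units).
#'
#' @param params An [iocsf_params()].
#' @param f_lo,f_hi Integration bounds, cycles/degree. Defaults cover the
#'   tested range 0.94 to 2.54 c/d.
#' @param n_grid Number of grid points (>= 2).
#' @return The area, a scalar >= 0.
#' @export
aulio_csf <- function(params, f_lo = 0.94, f_hi = 2.54, n_grid = 100) {
  if (!(f_lo > 0 && f_hi > f_lo)) stop("need 0 < f_lo < f_hi")
  if (n_grid < 2) stop("n_grid must be at least 2")
  lf <- seq(log10(f_lo), log10(f_hi), length.out = n_grid)
  s <- pmax(log_sensitivity(10^lf, params), 0)
  h <- lf[2] - lf[1]
  h * (sum(s) - (s[1] + s[n_grid]) / 2)
}

#' Tidy a sensitivity-function parameter set
#'
#' @param x An [iocsf_params()].
#' @param ... Unused.
#' @return A tibble with one row per parameter.
#' @export
tidy.iocsf_params <- function(x, ...) {
  tibble::tibble(
    term = c("gamma_max", "f_max", "beta_octaves", "trunc_delta"),
    estimate = c(x$gamma_max, x$f_max, x$beta_octaves, x$trunc_delta),
    unit = c("linear sensitivity", "cycles/degree", "octaves", "log10 units"))
}

#' Sensitivity-function curve plot
#'
#' @param object An [iocsf_params()].
#' @param f_lo,f_hi Frequency range to draw, cycles/degree.
#' @param ... Unused.
#' @return A ggplot object (log10 axes).
#' @export
autoplot.iocsf_params <- function(object, f_lo = 0.25, f_hi = 8, ...) {
  f <- 10^seq(log10(f_lo), log10(f_hi), length.out = 200)
  df <- tibble::tibble(f = f, sensitivity = 10^log_sensitivity(f, object))
  ggplot2::ggplot(df, ggplot2::aes(.data$f, .data$sensitivity)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "spatial frequency (c/d)",
                  y = "interocular correlation sensitivity")
}

#' Serialize sensitivity-function parameters to JSON
#'
#' Plain-text key-value record with explicit units; round-trips through
#' [read_iocsf_params()].
#'
#' @param params An [iocsf_params()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_iocsf_params <- function(params, path) {
  jsonlite::write_json(
    list(gamma_max = params$gamma_max, f_max_cpd = params$f_max,
         beta_octaves = params$beta_octaves,
         trunc_delta_log10 = params$trunc_delta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_iocsf_params
#' @export
read_iocsf_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  iocsf_params(x$gamma_max, x$f_max_cpd, x$beta_octaves, x$trunc_delta_log10)
}
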