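#' Perceived phase under a weighted-summation binocular observer
#'
#' The cyclopean percept of two horizontal gratings at equal-and-opposite
#' phase shifts is modelled as an amplitude-weighted vector sum. With
#' effective amplitudes `a_d = weight_dom * contrast_ratio` (dominant eye)
#' and `a_n = weight_nondom` (nondominant eye, contrast fixed at 100%),
#' configuration 1 gives
#' `phi = atan(((a_d - a_n) / (a_d + a_n)) * tan(theta0))` and configuration
#' 2 the negative. Balanced amplitudes give a zero-phase percept; the
#' percept is bounded by `±theta0` and positive phase follows the
#' dominant-eye component.
#'
#' @param weight_dom,weight_nondom Positive eye gains.
#' @param contrast_ratio Dominant-eye contrast multiplier `delta` in
#'   `(0, 1]`.
#' @param theta0 Half phase offset, degrees, in `(0, 90)`.
#' @param configuration 1 or 2.
#' @return Perceived phase, degrees.
#' @examples
#' perceived_phase_model(2, 1)        # dominant eye twice the weight
#' perceived_phase_model(1, 1)        # balanced: 0
#' @export
perceived_phase_model <- function(weight_dom, weight_nondom,
                                  contrast_ratio = 1, theta0 = 22.5,
                                  configuration = 1) {
  a_d <- weight_dom * contrast_ratio
  a_n <- weight_nondom
  if (any(a_d <= 0) || any(a_n <= 0)) stop("effective amplitudes must be positive")
  if (theta0 <= 0 || theta0 >= 90) stop("theta0 must lie in (0, 90) degrees")
  if (!all(configuration %in% c(1, 2))) stop("configuration must be 1 or 2")
  phi <- atan(((a_d - a_n) / (a_d + a_n)) * tan(theta0 * pi / 180)) * 180 / pi
  ifelse(configuration == 1, phi, -phi)
}

#' Combine the two stimulus configurations
#'
#' The session value is `(phi_config1 - phi_config2) / 2`: any additive
#' report bias common to both configurations (e.g. a positional error in the
#' adjustment) cancels exactly, while the antisymmetric phase signal is
#' preserved.
#'
#' @param phi_config1,phi_config2 Reported phases, degrees (vectorised).
#' @return Combined perceived phase, degrees.
#' @export
combine_configurations <- function(phi_config1, phi_config2) {
  (phi_config1 - phi_config2) / 2
}

#' Simulate one phase-combination measurement session
#'
#' Runs `repetitions` trials of each configuration: the model phase plus
#' seeded Gaussian adjustment noise per trial, optionally quantised to the
#' pixel grid of the reference-line report. Per-repetition configuration
#' pairs are combined and averaged into the session's perceived phase.
#'
#' @param observer An [observer_spec()], or any list with `weight_dom`,
#'   `weight_nondom` fields.
#' @param contrast_ratio Dominant-eye contrast multiplier in `(0, 1]`.
#' @param repetitions Repetitions per configuration (default 8, i.e. 16
#'   trials).
#' @param noise_sd Adjustment noise SD per trial, degrees.
#' @param seed Integer seed.
#' @param theta0 Half phase offset, degrees.
#' @param quantize_deg Optional report quantum in degrees
#'   (`360 / pixels-per-period`); `NULL` disables quantisation.
#' @param session_label Label attached to the result.
#' @return A list of class `phase_session` with `perceived_phase` (degrees),
#'   `n_trials` and the trial log tibble (`configuration`, `repetition`,
#'   `reported_phase`).
#' @export
simulate_phase_session <- function(observer, contrast_ratio = 1,
                                   repetitions = 8, noise_sd = 4,
                                   seed = 1L, theta0 = 22.5,
                                   quantize_deg = NULL,
                                   session_label = "pre") {
  if (repetitions < 1) stop("repetitions must be at least 1")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  phi <- vapply(c(1, 2), function(cfg)
    perceived_phase_model(observer$weight_dom, observer$weight_nondom,
                          contrast_ratio, theta0, cfg), numeric(1))
  noise <- with_local_seed(seed,
    matrix(stats::rnorm(2 * repetitions, 0, noise_sd), repetitions, 2))
  reported <- sweep(noise, 2, phi, "+")
  if (!is.null(quantize_deg))
    reported <- round(reported / quantize_deg) * quantize_deg
  combined <- combine_configurations(reported[, 1], reported[, 2])
  trials <- tibble::tibble(
    session_label = session_label,
    configuration = rep(c(1L, 2L), each = repetitions),
    repetition = rep(seq_len(repetitions), 2),
    reported_phase = c(reported[, 1], reported[, 2]))
  structure(list(session_label = session_label,
                 perceived_phase = mean(combined),
                 n_trials = 2L * repetitions,
                 trials = trials),
            class = "phase_session")
}

#' @export
print.phase_session <- function(x, ...) {
  cat(sprintf("Phase-combination session '%s': %.2f deg (%d trials)\n",
              x$session_label, x$perceived_phase, x$n_trials))
  invisible(x)
}

#' Calibrate the balanced interocular contrast ratio
#'
#' Finds the dominant-eye contrast multiplier `delta*` at which the
#' noise-free perceived phase is zero (balanced contribution of the two
#' eyes), by bisection on `(0, 1]`. Analytically `delta* =
#' weight_nondom / weight_dom`; when that exceeds 1 — the nominally
#' nondominant eye actually carries more weight — the ratio is clipped to 1
#' and flagged.
#'
#' @param observer A list with `weight_dom`, `weight_nondom`.
#' @param tolerance Phase tolerance, degrees.
#' @param theta0 Half phase offset, degrees.
#' @return A list with `contrast_ratio`, the residual `phase` at that ratio,
#'   and logical `clipped`.
#' @export
calibrate_balance_ratio <- function(observer, tolerance = 1e-6,
                                    theta0 = 22.5) {
  if (tolerance <= 0) stop("tolerance must be positive")
  phase_at <- function(d)
    perceived_phase_model(observer$weight_dom, observer$weight_nondom,
                          d, theta0, 1)
  if (phase_at(1) < 0) {
    warning("nondominant eye outweighs the dominant eye even at full ",
            "contrast; returning contrast_ratio = 1 (eyes mislabelled?)")
    return(list(contrast_ratio = 1, phase = phase_at(1), clipped = TRUE))
  }
  lo <- 1e-12; hi <- 1
  while (abs(phase_at((lo + hi) / 2)) >= tolerance) {
    mid <- (lo + hi) / 2
    if (phase_at(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < .Machine$double.eps) break
  }
  d <- (lo + hi) / 2
  list(contrast_ratio = d, phase = phase_at(d), clipped = FALSE)
}

#' Write phase-combination trial logs as CSV
#'
#' One row per trial: `session_label, configuration, repetition,
#' reported_phase`, plus a `subject_id` column when given.
#'
#' @param sessions A list of `phase_session` objects (or a single one).
#' @param path File path.
#' @param subject_id Optional subject identifier recycled over sessions.
#' @return Invisibly `path`.
#' @export
write_phase_trials <- function(sessions, path, subject_id = NULL) {
  if (inherits(sessions, "phase_session")) sessions <- list(sessions)
  df <- purrr::map_dfr(sessions, "trials")
  if (!is.null(subject_id)) df <- dplyr::mutate(df, subject_id = subject_id,
                                                .before = 1)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
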