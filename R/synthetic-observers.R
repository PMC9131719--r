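#' Ground-truth generative observer
#'
#' Bundles everything needed to simulate one subject in both paradigms: the
#' true sensitivity-function parameters and psychometrics for the adaptive
#' correlation task, per-eye gain weights and adjustment noise for the
#' phase-combination task, and the deprivation-effect parameters (zero
#' amplitude under the null model).
#'
#' @param iocsf_true An [iocsf_params()].
#' @param weight_dom,weight_nondom Baseline eye gains (> 0).
#' @param lapse Lapse rate in `[0, 0.1)`.
#' @param psychometric_slope Weibull slope.
#' @param phase_noise_sd Per-trial adjustment noise, degrees.
#' @param effect_amplitude Immediate post-deprivation perceived-phase shift,
#'   degrees (0 under the null model).
#' @param effect_tau Decay time constant of the effect, minutes.
#' @param iocsf_effect Multiplicative peak-gain factor immediately after
#'   deprivation (1 under the null model).
#' @param subject_id Identifier.
#' @param seed Integer seed from which all of this subject's measurement
#'   seeds are derived.
#' @return A list of class `observer_spec`.
#' @export
observer_spec <- function(iocsf_true = iocsf_params(),
                          weight_dom = 1, weight_nondom = 1,
                          lapse = 0.04, psychometric_slope = 3.5,
                          phase_noise_sd = 4,
                          effect_amplitude = 0, effect_tau = 15,
                          iocsf_effect = 1,
                          subject_id = "s01", seed = 1L) {
  stopifnot(inherits(iocsf_true, "iocsf_params"),
            weight_dom > 0, weight_nondom > 0,
            lapse >= 0, lapse < 0.1, psychometric_slope > 0,
            phase_noise_sd >= 0, effect_tau > 0, iocsf_effect > 0)
  structure(list(iocsf_true = iocsf_true, weight_dom = weight_dom,
                 weight_nondom = weight_nondom, lapse = lapse,
                 psychometric_slope = psychometric_slope,
                 phase_noise_sd = phase_noise_sd,
                 effect_amplitude = effect_amplitude,
                 effect_tau = effect_tau, iocsf_effect = iocsf_effect,
                 subject_id = subject_id, seed = as.integer(seed)),
            class = "observer_spec")
}

#' Deprivation-effect time course
#'
#' Exponentially decaying ocular-dominance shift:
#' `amplitude * exp(-t / tau)` degrees of perceived-phase shift at `t`
#' minutes after deprivation ends. Under the null model (amplitude 0) the
#' effect is identically zero.
#'
#' @param effect_amplitude Immediate shift, degrees.
#' @param effect_tau Decay constant, minutes (> 0).
#' @param t_minutes Time since end of deprivation, minutes (>= 0,
#'   vectorised).
#' @return Phase shift, degrees.
#' @export
effect_timecourse <- function(effect_amplitude, effect_tau, t_minutes) {
  if (any(t_minutes < 0)) stop("t_minutes must be nonnegative")
  if (effect_tau <= 0) stop("effect_tau must be positive")
  effect_amplitude * exp(-t_minutes / effect_tau)
}

#' Per-eye occlusion schedule of square-wave alternate deprivation
#'
#' For square-wave alternation at `frequency_hz` with the given duty cycle,
#' each eye is open for `duty * 1000 / frequency_hz` ms per cycle and
#' occluded while the fellow eye is open. At 7 Hz with a 50/50 split this is
#' 1000/14 = 71.4 ms, conventionally reported as 71 ms.
#'
#' @param frequency_hz Alternation frequency, Hz (> 0).
#' @param duty Fraction of each cycle one eye is open, in `(0, 1)`.
#' @return A list with `open_ms`, `occluded_ms` (exact) and
#'   `occluded_ms_rounded`.
#' @export
alternation_schedule <- function(frequency_hz = 7, duty = 0.5) {
  if (frequency_hz <= 0) stop("frequency_hz must be positive")
  if (duty <= 0 || duty >= 1) stop("duty must lie in (0, 1)")
  open_ms <- duty * 1000 / frequency_hz
  list(frequency_hz = frequency_hz, duty = duty,
       open_ms = open_ms,
       occluded_ms = (1 - duty) * 1000 / frequency_hz,
       occluded_ms_rounded = round(open_ms))
}

# default population-level generative settings; every entry can be
# overridden through `population_params`
default_population <- function() {
  list(gamma_max_mean = 10, gamma_max_log10_sd = 0.08,
       f_max_mean = 1.5, f_max_log10_sd = 0.06,
       beta_mean = 3, beta_sd = 0.3,
       delta_mean = 0.5, delta_sd = 0.1,
       imbalance_log_sd = 0.15,
       lapse = 0.04, psychometric_slope = 3.5,
       phase_noise_sd = 4,
       effect_mean = 19.2, effect_sd = 7.0, effect_tau = 15,
       iocsf_effect = 1)
}

#' Generate a cohort of synthetic observers
#'
#' Draws `n` subjects from the configured population distributions. Under
#' the null model every deprivation effect is zero (`effect_amplitude = 0`,
#' `iocsf_effect = 1`), matching a cohort whose binocular balance and
#' correlation sensitivity do not change. Under the deprivation model the
#' immediate perceived-phase shift is drawn from
#' `Normal(effect_mean, effect_sd)` — by default the 19.2 ± 7.0 degree
#' immediate effect reported for 2.5 h of monocular deprivation — and
#' decays with time constant `effect_tau`.
#'
#' @param n Cohort size (>= 2).
#' @param model `"null"` or `"deprivation"`.
#' @param population_params Named list overriding entries of the default
#'   population settings (see Details in the package vignette).
#' @param seed Integer master seed; cohorts are fully reproducible.
#' @return A list of class `observer_cohort` of [observer_spec()] objects,
#'   with the generating settings attached.
#' @export
make_cohort <- function(n = 10, model = c("null", "deprivation"),
                        population_params = list(), seed = 1L) {
  model <- match.arg(model)
  if (n < 2) stop("cohort size must be at least 2")
  pop <- utils::modifyList(default_population(), population_params)
  obs <- with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      gmax <- pop$gamma_max_mean * 10^stats::rnorm(1, 0, pop$gamma_max_log10_sd)
      fmax <- pop$f_max_mean * 10^stats::rnorm(1, 0, pop$f_max_log10_sd)
      beta <- max(stats::rnorm(1, pop$beta_mean, pop$beta_sd), 1)
      delt <- max(stats::rnorm(1, pop$delta_mean, pop$delta_sd), 0)
      imb <- abs(stats::rnorm(1, 0, pop$imbalance_log_sd))
      amp <- if (model == "deprivation")
        stats::rnorm(1, pop$effect_mean, pop$effect_sd) else 0
      ioc_eff <- if (model == "deprivation") pop$iocsf_effect else 1
      observer_spec(
        iocsf_true = iocsf_params(max(gmax, 1.01), fmax, beta, delt),
        weight_dom = 1, weight_nondom = exp(-imb),
        lapse = pop$lapse, psychometric_slope = pop$psychometric_slope,
        phase_noise_sd = pop$phase_noise_sd,
        effect_amplitude = amp, effect_tau = pop$effect_tau,
        iocsf_effect = ioc_eff,
        subject_id = sprintf("s%02d", i),
        seed = derive_seed(seed, 101L, i))
    })
  })
  structure(obs, class = "observer_cohort", model = model,
            population = pop, seed = as.integer(seed))
}

#' @export
print.observer_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d observers, '%s' model, seed %d\n",
              length(x), attr(x, "model"), attr(x, "seed")))
  invisible(x)
}

#' Measurement protocol for a deprivation experiment
#'
#' One pre-deprivation session and five post-deprivation sessions at 0, 10,
#' 20, 30 and 40 minutes after 1 h of alternate monocular deprivation; each
#' session runs 16 phase-combination trials (2 configurations x 8
#' repetitions) and a 100-trial adaptive correlation-sensitivity estimate.
#'
#' @param post_times_min Post-deprivation measurement times, minutes.
#' @param phase_repetitions Phase-task repetitions per configuration.
#' @param qiocsf_trials Trials per adaptive session.
#' @param measures Character subset of `c("phase", "iocsf")`.
#' @param theta0 Half phase offset of the phase task, degrees.
#' @param grid,candidates Lattice and candidate set for the adaptive
#'   procedure (defaults built lazily).
#' @return A list of class `experiment_protocol`.
#' @export
experiment_protocol <- function(post_times_min = c(0, 10, 20, 30, 40),
                                phase_repetitions = 8,
                                qiocsf_trials = 100,
                                measures = c("phase", "iocsf"),
                                theta0 = 22.5,
                                grid = NULL, candidates = NULL) {
  measures <- match.arg(measures, several.ok = TRUE)
  stopifnot(all(post_times_min >= 0), phase_repetitions >= 1,
            qiocsf_trials >= 1)
  structure(list(post_times_min = post_times_min,
                 session_labels = c("pre", paste0("post", post_times_min)),
                 phase_repetitions = phase_repetitions,
                 qiocsf_trials = qiocsf_trials, measures = measures,
                 theta0 = theta0, grid = grid, candidates = candidates),
            class = "experiment_protocol")
}

# Invert the vector-sum model: the weight ratio a_d/a_n giving a target
# noise-free phase. Targets are clipped just inside the model's +/- theta0
# bound (the paradigm cannot report a phase beyond the disparity of its
# half-images).
weight_ratio_for_phase <- function(phase_deg, theta0 = 22.5,
                                   margin = 0.995) {
  phase_deg <- pmin(pmax(phase_deg, -theta0 * margin), theta0 * margin)
  T <- tan(phase_deg * pi / 180) / tan(theta0 * pi / 180)
  (1 + T) / (1 - T)
}

#' Simulate a full deprivation experiment on a cohort
#'
#' For every subject: calibrate the balanced contrast ratio from the
#' baseline weights, then measure each session of the protocol. The
#' deprivation effect enters as a target perceived-phase shift (negative:
#' the alternately-deprived dominant eye strengthening makes the percept
#' follow it, mirroring the sign convention under which monocular
#' deprivation drives the phase more negative), converted to an
#' instantaneous weight change by inverting the vector-sum model; the peak
#' gain of the sensitivity function is scaled towards `iocsf_effect` with
#' the same exponential time course. All measurement seeds derive from the
#' subject seed and session index.
#'
#' @param cohort An [make_cohort()] result (or list of [observer_spec()]).
#' @param protocol An [experiment_protocol()].
#' @return A list of class `experiment_dataset`: tibble `data` (one row per
#'   subject x session: `perceived_phase`, fitted parameters, `aulio`),
#'   `phase_trials` and `qiocsf_trials` logs, plus cohort metadata.
#' @export
simulate_experiment <- function(cohort, protocol = experiment_protocol()) {
  stopifnot(inherits(protocol, "experiment_protocol"))
  run_iocsf <- "iocsf" %in% protocol$measures
  run_phase <- "phase" %in% protocol$measures
  grid <- protocol$grid
  candidates <- protocol$candidates
  engine <- NULL
  if (run_iocsf) {
    if (is.null(grid)) grid <- posterior_grid()
    if (is.null(candidates)) candidates <- qiocsf_candidates()
    candidates <- dplyr::arrange(tibble::as_tibble(candidates),
                                 .data$fm, .data$M)
    engine <- qiocsf_engine(grid, candidates)
  }
  times <- c(NA, protocol$post_times_min)
  labels <- protocol$session_labels

  per_subject <- purrr::map(cohort, function(obs) {
    cal <- calibrate_balance_ratio(obs, theta0 = protocol$theta0)
    rows <- vector("list", length(labels))
    ptrials <- vector("list", length(labels))
    qtrials <- vector("list", length(labels))
    for (k in seq_along(labels)) {
      t_min <- times[k]
      shift <- if (is.na(t_min)) 0 else
        -effect_timecourse(obs$effect_amplitude, obs$effect_tau, t_min)
      row <- tibble::tibble(subject_id = obs$subject_id,
                            session = labels[k], time_min = t_min,
                            perceived_phase = NA_real_,
                            gamma_max = NA_real_, f_max = NA_real_,
                            beta_octaves = NA_real_, trunc_delta = NA_real_,
                            aulio = NA_real_)
      if (run_phase) {
        ratio <- weight_ratio_for_phase(shift, protocol$theta0)
        shifted <- obs
        shifted$weight_dom <- obs$weight_nondom * ratio / cal$contrast_ratio
        ses <- simulate_phase_session(
          shifted, contrast_ratio = cal$contrast_ratio,
          repetitions = protocol$phase_repetitions,
          noise_sd = obs$phase_noise_sd,
          seed = derive_seed(obs$seed, 1L, k),
          theta0 = protocol$theta0, session_label = labels[k])
        row$perceived_phase <- ses$perceived_phase
        ptrials[[k]] <- dplyr::mutate(ses$trials,
                                      subject_id = obs$subject_id,
                                      .before = 1)
      }
      if (run_iocsf) {
        g_t <- if (is.na(t_min)) 1 else
          1 + (obs$iocsf_effect - 1) * exp(-t_min / obs$effect_tau)
        truth <- obs$iocsf_true
        truth$gamma_max <- max(truth$gamma_max * g_t, 1.01)
        fit <- run_qiocsf_session(truth,
                                  n_trials = protocol$qiocsf_trials,
                                  seed = derive_seed(obs$seed, 2L, k),
                                  grid = grid, candidates = candidates,
                                  lapse = obs$lapse,
                                  slope = obs$psychometric_slope,
                                  engine = engine)
        row$gamma_max <- fit$params$gamma_max
        row$f_max <- fit$params$f_max
        row$beta_octaves <- fit$params$beta_octaves
        row$trunc_delta <- fit$params$trunc_delta
        row$aulio <- aulio_csf(fit$params)
        qtrials[[k]] <- dplyr::mutate(fit$trials,
                                      subject_id = obs$subject_id,
                                      session = labels[k], .before = 1)
      }
      rows[[k]] <- row
    }
    list(rows = dplyr::bind_rows(rows),
         ptrials = dplyr::bind_rows(ptrials),
         qtrials = dplyr::bind_rows(qtrials))
  })

  structure(list(
    data = purrr::map_dfr(per_subject, "rows"),
    phase_trials = purrr::map_dfr(per_subject, "ptrials"),
    qiocsf_trials = purrr::map_dfr(per_subject, "qtrials"),
    model = attr(cohort, "model") %||% "custom",
    cohort_seed = attr(cohort, "seed"),
    protocol = protocol), class = "experiment_dataset")
}

#' @export
print.experiment_dataset <- function(x, ...) {
  cat(sprintf("Simulated experiment: %d subjects x %d sessions ('%s' model)\n",
              dplyr::n_distinct(x$data$subject_id),
              dplyr::n_distinct(x$data$session), x$model))
  invisible(x)
}

#' Tidy an experiment dataset
#'
#' @param x An `experiment_dataset`.
#' @param ... Unused.
#' @return The per-subject, per-session tibble with sessions ordered on the
#'   measurement schedule.
#' @export
tidy.experiment_dataset <- function(x, ...) {
  dplyr::mutate(x$data, session = factor(.data$session,
                levels = x$protocol$session_labels))
}

#' Session-course plot of an experiment dataset
#'
#' @param object An `experiment_dataset`.
#' @param measure `"phase"` or `"aulio"`.
#' @param ... Unused.
#' @return A ggplot object: per-subject traces plus the group mean.
#' @export
autoplot.experiment_dataset <- function(object, measure = c("phase", "aulio"),
                                        ...) {
  measure <- match.arg(measure)
  col <- if (measure == "phase") "perceived_phase" else "aulio"
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$session, .data[[col]])) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                       alpha = 0.35) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", linewidth = 1) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "point", size = 2) +
    ggplot2::labs(x = "session",
                  y = if (measure == "phase")
                    "perceived phase (deg)" else "area under log SF")
}
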