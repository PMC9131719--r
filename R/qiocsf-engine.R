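#' Probability of a correct 2AFC orientation judgement
#'
#' Weibull psychometric link for the two-alternative orientation task with
#' guess rate 0.5:
#' `p = 0.5 + (0.5 - lapse) * (1 - exp(-(M * 10^S(f))^slope))`.
#' At the modulation threshold `M_t = 10^(-S(f))` the exponent is 1, so
#' performance sits at `0.5 + (0.5 - lapse) * (1 - 1/e)`.
#'
#' @param M Modulation in `[0, 1]` (vectorised).
#' @param f Spatial frequency, cycles/degree.
#' @param params An [iocsf_params()].
#' @param lapse Lapse rate in `[0, 0.1)`; caps the upper asymptote at
#'   `1 - lapse`.
#' @param slope Weibull slope (> 0).
#' @return Probability of a correct response.
#' @export
prob_correct <- function(M, f, params, lapse = 0.04, slope = 3.5) {
  if (any(M < 0 | M > 1)) stop("M must lie in [0, 1]")
  if (lapse < 0 || lapse >= 0.1) stop("lapse must lie in [0, 0.1)")
  if (slope <= 0) stop("slope must be positive")
  s <- log_sensitivity(f, params)
  0.5 + (0.5 - lapse) * (1 - exp(-(M * 10^s)^slope))
}

# same link over a parameter lattice (vectors per parameter), scalar (M, f)
prob_correct_grid <- function(M, f, theta, lapse, slope) {
  s <- log_sensitivity_grid(f, theta$gamma_max, theta$f_max,
                            theta$beta_octaves, theta$trunc_delta)
  0.5 + (0.5 - lapse) * (1 - exp(-(M * 10^s)^slope))
}

#' Discrete joint posterior over sensitivity-function parameters
#'
#' Builds the 4-D lattice (peak gain and peak frequency log-spaced;
#' bandwidth and truncation linear) with independent marginal priors,
#' uniform on each axis by default. The fitted psychometric nuisance
#' parameters (`lapse`, `slope`) are fixed constants of the model, stored
#' with the grid.
#'
#' @param gamma_max,f_max,beta_octaves,trunc_delta Axis grids (strictly
#'   increasing numeric vectors). Defaults follow the package's standard
#'   lattice: gamma in `[2, 200]` (12 log-spaced), peak frequency in
#'   `[0.5, 5]` c/d (12 log-spaced), bandwidth in `[1, 6]` octaves (8),
#'   truncation in `[0, 1.5]` (8).
#' @param priors Optional named list of marginal prior weight vectors (one
#'   per axis, same lengths); uniform when omitted.
#' @param lapse,slope Psychometric nuisance constants of the fitting model.
#' @return A list of class `posterior_grid` with `axes`, the expanded
#'   parameter table `theta`, and probability vector `mass`.
#' @export
posterior_grid <- function(gamma_max = 10^seq(log10(2), log10(200), length.out = 12),
                           f_max = 10^seq(log10(0.5), log10(5), length.out = 12),
                           beta_octaves = seq(1, 6, length.out = 8),
                           trunc_delta = seq(0, 1.5, length.out = 8),
                           priors = NULL, lapse = 0.04, slope = 3.5) {
  axes <- list(gamma_max = gamma_max, f_max = f_max,
               beta_octaves = beta_octaves, trunc_delta = trunc_delta)
  for (nm in names(axes)) {
    ax <- axes[[nm]]
    if (length(ax) < 1 || any(diff(ax) <= 0))
      stop("axis '", nm, "' must be nonempty and strictly increasing")
  }
  w <- lapply(names(axes), function(nm) {
    p <- if (is.null(priors)) NULL else priors[[nm]]
    if (is.null(p)) p <- rep(1, length(axes[[nm]]))
    if (length(p) != length(axes[[nm]]) || any(p < 0) || sum(p) == 0)
      stop("invalid prior for axis '", nm, "'")
    p / sum(p)
  })
  theta <- expand.grid(gamma_max = gamma_max, f_max = f_max,
                       beta_octaves = beta_octaves,
                       trunc_delta = trunc_delta,
                       KEEP.OUT.ATTRS = FALSE)
  mass <- expand.grid(w[[1]], w[[2]], w[[3]], w[[4]],
                      KEEP.OUT.ATTRS = FALSE)
  mass <- mass[[1]] * mass[[2]] * mass[[3]] * mass[[4]]
  structure(list(axes = axes, theta = theta, mass = mass / sum(mass),
                 lapse = lapse, slope = slope),
            class = "posterior_grid")
}

#' @export
print.posterior_grid <- function(x, ...) {
  cat("Posterior over sensitivity-function parameters:",
      paste(vapply(x$axes, length, 1L), collapse = " x "),
      sprintf("lattice (%d cells), entropy %.3f nats\n",
              length(x$mass), posterior_entropy(x)))
  invisible(x)
}

#' Shannon entropy of a posterior grid
#'
#' @param posterior A [posterior_grid()].
#' @return Entropy in nats.
#' @export
posterior_entropy <- function(posterior) {
  m <- posterior$mass[posterior$mass > 0]
  -sum(m * log(m))
}

#' Bayes update of the posterior after one trial
#'
#' Multiplies the mass at each lattice point by the likelihood of the
#' observed response under that parameter set (the psychometric probability
#' if correct, its complement if not) and renormalises.
#'
#' @param posterior A [posterior_grid()].
#' @param trial A list or one-row data frame with `fm` (cycles/degree), `M`,
#'   and logical `response_correct`.
#' @return The updated `posterior_grid`.
#' @export
update_posterior <- function(posterior, trial) {
  stopifnot(inherits(posterior, "posterior_grid"))
  p <- prob_correct_grid(trial$M, trial$fm, posterior$theta,
                         posterior$lapse, posterior$slope)
  lik <- if (isTRUE(trial$response_correct)) p else 1 - p
  m <- posterior$mass * lik
  tot <- sum(m)
  if (!is.finite(tot) || tot <= 0)
    stop("posterior update failed: likelihood numerically zero over the ",
         "whole lattice (trial fm=", trial$fm, ", M=", trial$M, ")")
  posterior$mass <- m / tot
  posterior
}

#' Candidate stimulus set for the adaptive procedure
#'
#' @param n_f,n_M Numbers of frequencies and modulations.
#' @param f_range Frequency range, cycles/degree (log-spaced). Defaults to
#'   the tested range 0.94 to 2.54 c/d.
#' @param M_range Modulation range (log-spaced).
#' @return A tibble of `(fm, M)` pairs sorted by `fm` then `M`.
#' @export
qiocsf_candidates <- function(n_f = 12, n_M = 25,
                              f_range = c(0.94, 2.54),
                              M_range = c(0.02, 1)) {
  tidyr::expand_grid(
    fm = 10^seq(log10(f_range[1]), log10(f_range[2]), length.out = n_f),
    M = 10^seq(log10(M_range[1]), log10(M_range[2]), length.out = n_M))
}

# Precomputed psychometric matrices for one (grid, candidates) pairing.
# P[c, t] = P(correct | candidate c, theta t); C = P log P + (1-P) log(1-P)
# is the negative conditional response entropy, the only candidate-specific
# term in the expected posterior entropy.
qiocsf_engine <- function(posterior, candidates) {
  stopifnot(inherits(posterior, "posterior_grid"))
  if (nrow(candidates) == 0) stop("candidate set is empty")
  P <- t(vapply(seq_len(nrow(candidates)), function(i)
    prob_correct_grid(candidates$M[i], candidates$fm[i], posterior$theta,
                      posterior$lapse, posterior$slope),
    numeric(nrow(posterior$theta))))
  list(candidates = candidates, P = P,
       C = P * log(P) + (1 - P) * log1p(-P))
}

# expected posterior entropy (nats) for every candidate under `mass`
expected_entropies <- function(engine, mass) {
  pbar <- as.vector(engine$P %*% mass)
  qbar <- 1 - pbar
  mlm <- sum(ifelse(mass > 0, mass * log(mass), 0))
  pbar * log(pbar) + qbar * log(qbar) -
    as.vector(engine$C %*% mass) - mlm
}

#' Information-maximising stimulus selection
#'
#' Picks the candidate `(fm, M)` whose presentation minimises the expected
#' posterior entropy over the parameter lattice (one-step-ahead expected
#' information gain), ties broken by lowest frequency then lowest
#' modulation.
#'
#' @param posterior A [posterior_grid()].
#' @param candidates A tibble of `fm`, `M` pairs, e.g.
#'   [qiocsf_candidates()].
#' @return A one-row tibble with `fm`, `M` and the candidate's
#'   `expected_entropy` (nats).
#' @export
select_stimulus <- function(posterior, candidates) {
  if (is.null(candidates) || nrow(candidates) == 0)
    stop("candidate set is empty")
  candidates <- dplyr::arrange(tibble::as_tibble(candidates),
                               .data$fm, .data$M)
  eng <- qiocsf_engine(posterior, candidates)
  eh <- expected_entropies(eng, posterior$mass)
  best <- which(eh <= min(eh) + 1e-12)[1]  # first of any numerical ties
  tibble::tibble(fm = candidates$fm[best], M = candidates$M[best],
                 expected_entropy = eh[best])
}

#' Posterior point estimate of the sensitivity-function parameters
#'
#' Marginal posterior mean of each parameter — on the log10 scale for peak
#' gain and peak frequency, linear for bandwidth and truncation — or the
#' joint maximum a posteriori lattice point.
#'
#' @param posterior A [posterior_grid()].
#' @param method `"mean"` (default) or `"map"`.
#' @return An [iocsf_params()].
#' @export
posterior_estimate <- function(posterior, method = c("mean", "map")) {
  method <- match.arg(method)
  th <- posterior$theta
  m <- posterior$mass
  if (method == "map") {
    i <- which.max(m)
    est <- as.numeric(th[i, ])
  } else {
    est <- c(10^sum(m * log10(th$gamma_max)),
             10^sum(m * log10(th$f_max)),
             sum(m * th$beta_octaves),
             sum(m * th$trunc_delta))
  }
  iocsf_params(max(est[1], 1 + 1e-9), est[2], est[3], est[4])
}

#' Run one adaptive estimation session against a simulated observer
#'
#' The quick interocular-correlation sensitivity procedure: on each of
#' `n_trials` trials the information-maximising stimulus is selected, the
#' observer's 2AFC orientation response is simulated from its true
#' psychometric function, and the posterior is updated by Bayes' rule. Each
#' 1 s stimulus presentation is logged as metadata only.
#'
#' @param observer An [observer_spec()], or an [iocsf_params()] (then
#'   `lapse` and `slope` below describe the observer's true behaviour).
#' @param n_trials Number of trials (default 100).
#' @param seed Integer seed driving the simulated responses.
#' @param grid Prior lattice, a [posterior_grid()].
#' @param candidates Candidate stimuli, a tibble of `fm`, `M`.
#' @param lapse,slope True observer psychometrics when `observer` is a bare
#'   parameter set.
#' @param estimate `"mean"` or `"map"` point estimate.
#' @param engine Optional precomputed internal engine (reused across
#'   sessions that share `grid` and `candidates`); built when omitted.
#' @return A list of class `qiocsf_fit`: `params` (the estimate), `trials`
#'   (the trial log tibble), `posterior`, and `truth`.
#' @export
run_qiocsf_session <- function(observer, n_trials = 100, seed = 1L,
                               grid = posterior_grid(),
                               candidates = qiocsf_candidates(),
                               lapse = 0.04, slope = 3.5,
                               estimate = c("mean", "map"),
                               engine = NULL) {
  estimate <- match.arg(estimate)
  if (inherits(observer, "observer_spec")) {
    truth <- observer$iocsf_true
    lapse <- observer$lapse
    slope <- observer$psychometric_slope
  } else if (inherits(observer, "iocsf_params")) {
    truth <- observer
  } else stop("observer must be an observer_spec or iocsf_params")
  if (n_trials < 0) stop("n_trials must be nonnegative")

  candidates <- dplyr::arrange(tibble::as_tibble(candidates),
                               .data$fm, .data$M)
  if (is.null(engine)) engine <- qiocsf_engine(grid, candidates)
  mass <- grid$mass
  th <- grid$theta
  n_cand <- nrow(candidates)
  idx <- fm <- M <- numeric(n_trials)
  ori <- integer(n_trials)
  correct <- logical(n_trials)

  with_local_seed(seed, {
    for (i in seq_len(n_trials)) {
      eh <- expected_entropies(engine, mass)
      j <- which(eh <= min(eh) + 1e-12)[1]
      idx[i] <- j
      fm[i] <- candidates$fm[j]
      M[i] <- candidates$M[j]
      ori[i] <- sample(c(45L, 135L), 1)
      p_true <- prob_correct(M[i], fm[i], truth, lapse, slope)
      correct[i] <- stats::runif(1) < p_true
      lik <- if (correct[i]) engine$P[j, ] else 1 - engine$P[j, ]
      m <- mass * lik
      tot <- sum(m)
      if (!is.finite(tot) || tot <= 0)
        stop("posterior update failed at trial ", i)
      mass <- m / tot
    }
  })

  grid$mass <- mass
  trials <- tibble::tibble(trial_index = seq_len(n_trials), fm = fm, M = M,
                           orientation_true = ori,
                           response_correct = correct)
  attr(trials, "presentation_s") <- 1
  structure(list(params = posterior_estimate(grid, estimate),
                 trials = trials, posterior = grid, truth = truth,
                 seed = seed),
            class = "qiocsf_fit")
}

#' @export
print.qiocsf_fit <- function(x, ...) {
  cat(sprintf("Adaptive sensitivity-function fit (%d trials, %.0f%% correct)\n",
              nrow(x$trials), 100 * mean(x$trials$response_correct)))
  print(x$params)
  invisible(x)
}

#' Tidy an adaptive fit: estimates next to ground truth
#'
#' @param x A `qiocsf_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `truth`.
#' @export
tidy.qiocsf_fit <- function(x, ...) {
  dplyr::left_join(tidy(x$params),
                   dplyr::rename(tidy(x$truth), truth = "estimate"),
                   by = c("term", "unit")) |>
    dplyr::select("term", "estimate", "truth", "unit")
}

#' One-row summary of an adaptive fit
#'
#' @param x A `qiocsf_fit`.
#' @param ... Unused.
#' @return A tibble with trial count, proportion correct, posterior entropy
#'   and the area under the fitted log sensitivity function.
#' @export
glance.qiocsf_fit <- function(x, ...) {
  tibble::tibble(n_trials = nrow(x$trials),
                 prop_correct = mean(x$trials$response_correct),
                 posterior_entropy = posterior_entropy(x$posterior),
                 aulio = aulio_csf(x$params))
}

#' Plot an adaptive fit: estimated and true sensitivity functions
#'
#' @param object A `qiocsf_fit`.
#' @param ... Passed on to nothing; present for the generic.
#' @return A ggplot object.
#' @export
autoplot.qiocsf_fit <- function(object, ...) {
  f <- 10^seq(log10(0.5), log10(5), length.out = 200)
  df <- dplyr::bind_rows(
    tibble::tibble(f = f, curve = "estimated",
                   sensitivity = 10^log_sensitivity(f, object$params)),
    tibble::tibble(f = f, curve = "true",
                   sensitivity = 10^log_sensitivity(f, object$truth)))
  ggplot2::ggplot(df, ggplot2::aes(.data$f, .data$sensitivity,
                                   linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "spatial frequency (c/d)",
                  y = "interocular correlation sensitivity",
                  linetype = NULL)
}

#' Write / read a trial log as CSV
#'
#' Columns `trial_index, fm, M, orientation_true, response_correct`.
#'
#' @param trials A trial-log tibble (e.g. `fit$trials`).
#' @param path File path.
#' @return Invisibly `path`; `read_trial_log()` returns the tibble.
#' @export
write_trial_log <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
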