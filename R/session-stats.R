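#' Subtract each subject's baseline from every condition
#'
#' Converts raw per-session values to change scores: every cell minus the
#' same subject's value in the designated baseline condition. The baseline
#' column becomes identically zero and can be dropped from inferential
#' contrasts.
#'
#' @param data Long tibble with columns `subject`, `condition`, `value`
#'   (names configurable).
#' @param baseline Label of the baseline condition.
#' @param drop_baseline Drop the (all-zero) baseline rows from the result?
#' @param subject,condition,value Column names.
#' @return A tibble of change scores with the same columns.
#' @export
normalize_to_baseline <- function(data, baseline = "pre",
                                  drop_baseline = FALSE,
                                  subject = "subject",
                                  condition = "condition",
                                  value = "value") {
  stopifnot(all(c(subject, condition, value) %in% names(data)))
  base <- data[data[[condition]] == baseline, c(subject, value)]
  if (nrow(base) == 0) stop("baseline condition '", baseline, "' not found")
  names(base)[2] <- ".baseline"
  out <- dplyr::left_join(tibble::as_tibble(data), base, by = subject)
  if (anyNA(out$.baseline)) stop("some subjects lack a baseline value")
  out[[value]] <- out[[value]] - out$.baseline
  out$.baseline <- NULL
  if (drop_baseline) out <- out[out[[condition]] != baseline, ]
  out
}

# long tibble -> subjects x conditions matrix, complete and balanced
rm_matrix <- function(data, subject, condition, value, cond_levels = NULL) {
  s <- as.character(data[[subject]])
  cond <- data[[condition]]
  lv <- cond_levels %||% (if (is.factor(cond)) levels(cond)
                          else unique(as.character(cond)))
  cond <- as.character(cond)
  lv <- lv[lv %in% cond]
  if (anyNA(data[[value]])) stop("missing cells in the repeated-measures table")
  Y <- tapply(data[[value]], list(s, factor(cond, levels = lv)), identity)
  if (any(vapply(Y, length, 1L) != 1)) stop("duplicated subject x condition cells")
  Y <- matrix(unlist(Y), nrow = nrow(Y), dimnames = dimnames(Y))
  if (anyNA(Y)) stop("unbalanced design: missing subject x condition cells")
  if (nrow(Y) < 2 || ncol(Y) < 2)
    stop("need at least 2 subjects and 2 conditions")
  Y
}

# orthonormal contrast matrix (k x (k-1)), columns orthogonal to the mean
orthonormal_contrasts <- function(k) {
  H <- stats::contr.helmert(k)
  sweep(H, 2, sqrt(colSums(H^2)), "/")
}

# univariate within-subject test of one effect from its contrast scores
# Z (n x d): F, Greenhouse-Geisser epsilon, Mauchly's test
within_effect <- function(Z, label) {
  n <- nrow(Z); d <- ncol(Z)
  zbar <- colMeans(Z)
  ss_eff <- n * sum(zbar^2)
  R <- sweep(Z, 2, zbar)
  ss_err <- sum(R^2)
  df1 <- d; df2 <- d * (n - 1)
  S <- crossprod(R) / (n - 1)
  eps <- if (d == 1) 1 else
    min(sum(diag(S))^2 / (d * sum(S^2)), 1)
  if (d == 1 || n - 1 <= d) {
    mW <- NA_real_; m_p <- NA_real_
  } else {
    detS <- det(S)
    mW <- if (detS <= 0) 0 else detS / (sum(diag(S)) / d)^d
    # Box's asymptotic expansion (as in stats::mauchly.test), including the
    # second-order term
    nu <- n - 1
    rho <- 1 - (2 * d^2 + d + 2) / (6 * d * nu)
    w2 <- (d + 2) * (d - 1) * (d - 2) * (2 * d^3 + 6 * d^2 + 3 * d + 2) /
      (288 * d^2 * nu^2 * rho^2)
    chi2 <- -nu * rho * log(max(mW, .Machine$double.xmin))
    dfm <- d * (d + 1) / 2 - 1
    m_p <- stats::pchisq(chi2, dfm, lower.tail = FALSE) +
      w2 * (stats::pchisq(chi2, dfm + 4, lower.tail = FALSE) -
            stats::pchisq(chi2, dfm, lower.tail = FALSE))
  }
  degenerate <- ss_err <= 1e-12 * max(ss_eff, 1)
  Fv <- if (degenerate) NA_real_ else (ss_eff / df1) / (ss_err / df2)
  tibble::tibble(
    effect = label, ss_effect = ss_eff, ss_error = ss_err,
    df1 = df1, df2 = df2, statistic = Fv,
    p.value = if (degenerate) NA_real_ else
      stats::pf(Fv, df1, df2, lower.tail = FALSE),
    epsilon = eps,
    df1_gg = eps * df1, df2_gg = eps * df2,
    p.value_gg = if (degenerate) NA_real_ else
      stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE),
    mauchly_W = mW, mauchly_p = m_p, degenerate = degenerate)
}

finalize_rm_anova <- function(effects, sphericity, n) {
  effects$correction_applied <- switch(
    sphericity,
    never = FALSE,
    always = effects$df1 > 1,
    auto = effects$df1 > 1 & !is.na(effects$mauchly_p) &
      effects$mauchly_p < 0.05)
  structure(list(effects = effects, sphericity = sphericity, n = n),
            class = "rm_anova")
}

#' One-way repeated-measures ANOVA with sphericity correction
#'
#' Classical within-subject decomposition (condition effect against the
#' subject-by-condition interaction), computed from orthonormal contrast
#' scores. Mauchly's sphericity test is reported; when sphericity is
#' rejected at 0.05 (`sphericity = "auto"`, the default) — or always, or
#' never — the Greenhouse–Geisser epsilon multiplies both degrees of
#' freedom, yielding the familiar non-integer corrected df.
#'
#' @param data Long tibble with `subject`, `condition`, `value` columns
#'   (names configurable); every subject must have every condition exactly
#'   once.
#' @param sphericity `"auto"`, `"always"` or `"never"`.
#' @param subject,condition,value Column names.
#' @return An object of class `rm_anova`; see [tidy.rm_anova()].
#' @examples
#' df <- tidyr::expand_grid(subject = letters[1:5], condition = c("a", "b", "c"))
#' df$value <- rnorm(nrow(df))
#' rm_anova_one_way(df)
#' @export
rm_anova_one_way <- function(data, sphericity = c("auto", "always", "never"),
                             subject = "subject", condition = "condition",
                             value = "value") {
  sphericity <- match.arg(sphericity)
  Y <- rm_matrix(data, subject, condition, value)
  Z <- Y %*% orthonormal_contrasts(ncol(Y))
  finalize_rm_anova(within_effect(Z, "condition"), sphericity, nrow(Y))
}

#' Two-way fully-within repeated-measures ANOVA
#'
#' Both factors vary within subject (e.g. measurement time crossed with
#' spatial frequency). Main effects and the interaction are each tested
#' against their own subject interaction, with a per-effect
#' Greenhouse–Geisser correction gated (or forced) as in
#' [rm_anova_one_way()]. A factor with a single level degenerates the
#' analysis to the one-way case.
#'
#' @param data Long tibble with `subject`, two factor columns and `value`.
#' @param factor1,factor2 Names of the two within-subject factor columns.
#' @param sphericity `"auto"`, `"always"` or `"never"`.
#' @param subject,value Column names.
#' @return An object of class `rm_anova` with one row per effect.
#' @export
rm_anova_two_way <- function(data, factor1 = "time", factor2 = "frequency",
                             sphericity = c("auto", "always", "never"),
                             subject = "subject", value = "value") {
  sphericity <- match.arg(sphericity)
  stopifnot(all(c(subject, factor1, factor2, value) %in% names(data)))
  lv1 <- if (is.factor(data[[factor1]])) levels(data[[factor1]])
         else unique(as.character(data[[factor1]]))
  lv2 <- if (is.factor(data[[factor2]])) levels(data[[factor2]])
         else unique(as.character(data[[factor2]]))
  a <- length(lv1); b <- length(lv2)
  cond <- interaction(factor(data[[factor1]], lv1),
                      factor(data[[factor2]], lv2), sep = ":")
  dd <- tibble::tibble(subject = as.character(data[[subject]]),
                       condition = as.character(cond),
                       value = data[[value]])
  lv <- as.vector(outer(lv1, lv2, paste, sep = ":"))
  Y <- rm_matrix(dd, "subject", "condition", "value", cond_levels = lv)
  # columns of Y vary factor1 fastest, matching kronecker(H2, H1) ordering
  H1 <- if (a > 1) orthonormal_contrasts(a) else NULL
  H2 <- if (b > 1) orthonormal_contrasts(b) else NULL
  j1 <- matrix(1 / sqrt(a), a, 1); j2 <- matrix(1 / sqrt(b), b, 1)
  effects <- list()
  if (a > 1)
    effects[[factor1]] <- within_effect(Y %*% kronecker(j2, H1), factor1)
  if (b > 1)
    effects[[factor2]] <- within_effect(Y %*% kronecker(H2, j1), factor2)
  if (a > 1 && b > 1)
    effects[["interaction"]] <- within_effect(
      Y %*% kronecker(H2, H1), paste0(factor1, ":", factor2))
  if (length(effects) == 0) stop("both factors have a single level")
  finalize_rm_anova(dplyr::bind_rows(effects), sphericity, nrow(Y))
}

#' @export
print.rm_anova <- function(x, ...) {
  td <- tidy(x)
  cat("Repeated-measures ANOVA (n =", x$n, "subjects)\n")
  for (i in seq_len(nrow(td))) {
    cat(sprintf("  %s: F(%.4g, %.4g) = %.4g, p = %.4g%s\n",
                td$effect[i], td$df1[i], td$df2[i], td$statistic[i],
                td$p.value[i],
                if (td$correction_applied[i])
                  sprintf(" [Greenhouse-Geisser, eps = %.3f]", td$epsilon[i])
                else ""))
  }
  invisible(x)
}

#' Tidy a repeated-measures ANOVA
#'
#' @param x An `rm_anova`.
#' @param ... Unused.
#' @return A tibble with one row per effect; `df1`, `df2` and `p.value`
#'   reflect the Greenhouse–Geisser correction whenever it was applied
#'   (`correction_applied`), with the uncorrected values in `df1_unc`,
#'   `df2_unc`, `p.value_unc`.
#' @export
tidy.rm_anova <- function(x, ...) {
  e <- x$effects
  tibble::tibble(
    effect = e$effect, statistic = e$statistic,
    df1 = ifelse(e$correction_applied, e$df1_gg, e$df1),
    df2 = ifelse(e$correction_applied, e$df2_gg, e$df2),
    p.value = ifelse(e$correction_applied, e$p.value_gg, e$p.value),
    epsilon = e$epsilon, mauchly_W = e$mauchly_W,
    mauchly_p = e$mauchly_p,
    correction_applied = e$correction_applied,
    df1_unc = e$df1, df2_unc = e$df2, p.value_unc = e$p.value,
    degenerate = e$degenerate)
}

#' @rdname tidy.rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(n = x$n, n_effects = nrow(td),
                 min_p = suppressWarnings(min(td$p.value, na.rm = TRUE)),
                 sphericity_mode = x$sphericity)
}

#' BIC approximation to the Bayes factor for the null
#'
#' Fits two nested fixed-effect models to the long repeated-measures data
#' and approximates `BF01 = exp((BIC_alt - BIC_null) / 2)`, the evidence in
#' favour of the simpler (null) model. Values above 1 favour the null;
#' conventional bands label 3–10 substantial, 10–30 strong, 30–100 very
#' strong and >100 decisive evidence.
#'
#' @param data Long tibble with `subject`, `condition`, `value` columns.
#' @param null,alt Model formulas over those columns; the null terms must
#'   nest inside the alternative's.
#' @return A list of class `bf01` with `bf01`, both BICs, and the
#'   interpretation `band`.
#' @export
bf01_bic <- function(data, null = value ~ subject,
                     alt = value ~ subject + condition) {
  t0 <- attr(stats::terms(null), "term.labels")
  t1 <- attr(stats::terms(alt), "term.labels")
  if (!all(t0 %in% t1))
    stop("models are not nested: null terms ", paste(t0, collapse = ", "),
         " not all contained in the alternative")
  b0 <- stats::BIC(stats::lm(null, data = data))
  b1 <- stats::BIC(stats::lm(alt, data = data))
  bf <- exp((b1 - b0) / 2)
  structure(list(bf01 = bf, bic_null = b0, bic_alt = b1,
                 band = bf01_band(bf)), class = "bf01")
}

bf01_band <- function(bf) {
  if (bf < 1) "favours the alternative"
  else if (bf < 3) "anecdotal"
  else if (bf < 10) "substantial"
  else if (bf < 30) "strong"
  else if (bf < 100) "very strong"
  else "decisive"
}

#' @export
print.bf01 <- function(x, ...) {
  cat(sprintf("BF01 = %.3f (%s evidence for the null; BIC approximation)\n",
              x$bf01, x$band))
  invisible(x)
}

#' Specification of a paired-difference power analysis
#'
#' @param effect_mean Expected mean change, paradigm units (dB or degrees).
#' @param effect_sd Between-subject SD of the change, same units.
#' @param alpha Type-I error rate.
#' @param target_power Desired power.
#' @param tail `"one"` or `"two"`.
#' @return A list of class `power_spec`.
#' @export
power_spec <- function(effect_mean, effect_sd, alpha = 0.05,
                       target_power = 0.8, tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (effect_sd <= 0) stop("effect_sd must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (target_power <= 0 || target_power >= 1)
    stop("target_power must lie in (0, 1)")
  structure(list(effect_mean = effect_mean, effect_sd = effect_sd,
                 alpha = alpha, target_power = target_power, tail = tail),
            class = "power_spec")
}

#' Exact power of the one-sample (paired-difference) t test
#'
#' Noncentral-t power: with noncentrality `(effect_mean / effect_sd) *
#' sqrt(n)` and `n - 1` degrees of freedom, the probability that the t
#' statistic exceeds the central-t critical value at `alpha` (one tail) or
#' falls in either rejection region (two tails).
#'
#' @param spec A [power_spec()].
#' @param n Sample size (>= 2, vectorised).
#' @return Power in `(0, 1)`.
#' @examples
#' power_one_sample_t(power_spec(1.39, 1.24), n = 7)
#' @export
power_one_sample_t <- function(spec, n) {
  stopifnot(inherits(spec, "power_spec"))
  if (any(n < 2)) stop("n must be at least 2")
  ncp <- (spec$effect_mean / spec$effect_sd) * sqrt(n)
  df <- n - 1
  if (spec$tail == "one") {
    stats::pt(stats::qt(1 - spec$alpha, df), df, ncp, lower.tail = FALSE)
  } else {
    crit <- stats::qt(1 - spec$alpha / 2, df)
    stats::pt(crit, df, ncp, lower.tail = FALSE) + stats::pt(-crit, df, ncp)
  }
}

#' Minimum sample size reaching the target power
#'
#' Scans `n = 2, 3, ...` and returns the first sample size whose exact
#' noncentral-t power meets `target_power`.
#'
#' @param spec A [power_spec()].
#' @param n_max Upper bound of the scan.
#' @return The minimum `n` (integer).
#' @examples
#' min_sample_size_t(power_spec(1.39, 1.24))   # 7
#' min_sample_size_t(power_spec(19.2, 7.0))    # 3
#' @export
min_sample_size_t <- function(spec, n_max = 10000L) {
  stopifnot(inherits(spec, "power_spec"))
  if (spec$effect_mean == 0)
    stop("target power is unreachable with a zero effect")
  for (n in 2:n_max) {
    if (power_one_sample_t(spec, n) >= spec$target_power) return(n)
  }
  stop("target power not reached by n = ", n_max)
}

#' Analyse a simulated experiment the way the session statistics prescribe
#'
#' Baseline-normalises the chosen measure, runs the one-way
#' repeated-measures ANOVA over the post-deprivation change scores
#' (Greenhouse–Geisser gated by Mauchly's test by default, or over all six
#' sessions with `contrast = "all"`), and computes the BIC Bayes factor for
#' the null model of no session effect.
#'
#' @param dataset An [simulate_experiment()] result, or a tibble with
#'   `subject_id`, `session` and the measure column.
#' @param measure `"phase"` (perceived phase) or `"aulio"` (area under the
#'   log sensitivity function).
#' @param contrast `"post"` (change scores across post sessions only, the
#'   default) or `"all"` (all sessions including the zero baseline).
#' @param sphericity Passed to [rm_anova_one_way()].
#' @return A list of class `session_analysis` with the change-score table,
#'   the `rm_anova`, the `bf01`, and the options used.
#' @export
analyze_sessions <- function(dataset, measure = c("phase", "aulio"),
                             contrast = c("post", "all"),
                             sphericity = c("auto", "always", "never")) {
  measure <- match.arg(measure)
  contrast <- match.arg(contrast)
  sphericity <- match.arg(sphericity)
  df <- if (inherits(dataset, "experiment_dataset")) dataset$data else dataset
  col <- if (measure == "phase") "perceived_phase" else "aulio"
  stopifnot(col %in% names(df))
  lv <- if (inherits(dataset, "experiment_dataset"))
    dataset$protocol$session_labels else unique(as.character(df$session))
  tab <- tibble::tibble(subject = df$subject_id,
                        condition = factor(df$session, levels = lv),
                        value = df[[col]])
  changes <- normalize_to_baseline(tab, baseline = "pre",
                                   drop_baseline = (contrast == "post"))
  anova <- rm_anova_one_way(changes, sphericity = sphericity)
  bf <- bf01_bic(changes)
  structure(list(measure = measure, contrast = contrast,
                 changes = changes, anova = anova, bf01 = bf),
            class = "session_analysis")
}

#' @export
print.session_analysis <- function(x, ...) {
  cat(sprintf("Session analysis of %s changes (%s sessions)\n",
              x$measure,
              if (x$contrast == "post") "post-deprivation" else "all"))
  print(x$anova)
  print(x$bf01)
  invisible(x)
}

#' @rdname analyze_sessions
#' @param x A `session_analysis`.
#' @param ... Unused.
#' @return `glance()`: a one-row tibble with the headline F, df, p, epsilon
#'   and BF01.
#' @export
glance.session_analysis <- function(x, ...) {
  td <- tidy(x$anova)
  tibble::tibble(measure = x$measure, statistic = td$statistic[1],
                 df1 = td$df1[1], df2 = td$df2[1], p.value = td$p.value[1],
                 epsilon = td$epsilon[1],
                 correction_applied = td$correction_applied[1],
                 bf01 = x$bf01$bf01, bf01_band = x$bf01$band)
}

#' Per-frequency log sensitivities implied by the fitted parameter sets
#'
#' Expands each subject-session fit into log10 sensitivities at a set of
#' spatial frequencies — the long table feeding the two-way (time by
#' frequency) repeated-measures analysis.
#'
#' @param dataset An [simulate_experiment()] result with the adaptive
#'   measure present.
#' @param frequencies Spatial frequencies, cycles/degree.
#' @return A tibble `subject`, `time`, `frequency`, `value`.
#' @export
sensitivity_table <- function(dataset,
                              frequencies = 10^seq(log10(0.94), log10(2.54),
                                                   length.out = 6)) {
  df <- if (inherits(dataset, "experiment_dataset")) dataset$data else dataset
  if (anyNA(df$gamma_max)) stop("dataset lacks fitted sensitivity parameters")
  purrr::pmap_dfr(df[c("subject_id", "session", "gamma_max", "f_max",
                       "beta_octaves", "trunc_delta")],
    function(subject_id, session, gamma_max, f_max, beta_octaves,
             trunc_delta) {
      p <- iocsf_params(gamma_max, f_max, beta_octaves, trunc_delta)
      tibble::tibble(subject = subject_id, time = session,
                     frequency = sprintf("f%.3f", frequencies),
                     value = log_sensitivity(frequencies, p))
    })
}
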