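test_that("psychometric link hits chance, threshold and asymptote", {
  p <- iocsf_params(10, 1.5, 3, 0.5)
  expect_equal(prob_correct(0, 1.5, p), 0.5)
  # at threshold the Weibull exponent is exactly 1
  M_t <- modulation_threshold(1.5, p)
  expect_equal(prob_correct(M_t, 1.5, p, lapse = 0.04, slope = 3.5),
               0.7907755, tolerance = 1e-6)
  # strong stimulus approaches 1 - lapse
  expect_equal(prob_correct(1, 1.5, iocsf_params(1000, 1.5, 3, 0),
                            lapse = 0.04), 0.96, tolerance = 1e-6)
  expect_error(prob_correct(2, 1.5, p), "M must")
  expect_error(prob_correct(0.5, 1.5, p, lapse = 0.2), "lapse")
  expect_error(prob_correct(0.5, 1.5, p, slope = -1), "slope")
})

test_that("the prior lattice is uniform, normalised, with correct marginals", {
  g <- posterior_grid()
  expect_equal(length(g$mass), 12 * 12 * 8 * 8)
  expect_equal(unique(round(g$mass, 15)), 1 / 9216)
  expect_equal(sum(g$mass), 1, tolerance = 1e-12)
  # a non-uniform marginal prior is preserved on its axis
  w <- c(1, 2, 3)
  g2 <- posterior_grid(gamma_max = c(3, 10, 30), f_max = c(1, 2),
                       beta_octaves = c(2, 4), trunc_delta = c(0, 1),
                       priors = list(gamma_max = w))
  marg <- tapply(g2$mass, g2$theta$gamma_max, sum)
  expect_equal(as.numeric(marg), w / sum(w))
  expect_error(posterior_grid(gamma_max = c(3, 2)), "strictly increasing")
})

test_that("Bayes updates renormalise, commute, and match a hand table", {
  g <- tiny_grid()
  tr1 <- list(fm = 1.5, M = 0.4, response_correct = TRUE)
  tr2 <- list(fm = 2, M = 0.1, response_correct = FALSE)
  g12 <- update_posterior(update_posterior(g, tr1), tr2)
  g21 <- update_posterior(update_posterior(g, tr2), tr1)
  expect_equal(sum(g12$mass), 1, tolerance = 1e-12)
  expect_equal(g12$mass, g21$mass, tolerance = 1e-12)

  # brute-force Bayes table computed cell by cell from first principles
  lik <- vapply(seq_len(nrow(g$theta)), function(i) {
    th <- g$theta[i, ]
    p <- oracle_prob_correct(0.4, 1.5, th$gamma_max, th$f_max,
                             th$beta_octaves, th$trunc_delta)
    p
  }, numeric(1))
  hand <- g$mass * lik
  hand <- hand / sum(hand)
  expect_equal(update_posterior(g, tr1)$mass, hand, tolerance = 1e-12)
})

test_that("a flat likelihood leaves the posterior unchanged", {
  g <- tiny_grid()
  # M = 0 is pure guessing under every parameter set
  g2 <- update_posterior(g, list(fm = 1.5, M = 0, response_correct = TRUE))
  expect_equal(g2$mass, g$mass, tolerance = 1e-14)
})

test_that("stimulus selection matches exhaustive entropy enumeration", {
  g <- tiny_grid()
  # sharpen the posterior a little so the choice is non-trivial
  for (k in 1:3)
    g <- update_posterior(g, list(fm = 1.5, M = 0.4, response_correct = TRUE))
  cand <- tiny_candidates()

  exhaustive <- vapply(seq_len(nrow(cand)), function(ci) {
    pr <- vapply(seq_len(nrow(g$theta)), function(i) {
      th <- g$theta[i, ]
      oracle_prob_correct(cand$M[ci], cand$fm[ci], th$gamma_max, th$f_max,
                          th$beta_octaves, th$trunc_delta)
    }, numeric(1))
    ent <- function(m) { m <- m[m > 0]; -sum(m * log(m)) }
    pbar <- sum(g$mass * pr)
    post_c <- g$mass * pr / pbar
    post_i <- g$mass * (1 - pr) / (1 - pbar)
    pbar * ent(post_c) + (1 - pbar) * ent(post_i)
  }, numeric(1))

  sel <- select_stimulus(g, cand)
  best <- which.min(exhaustive)
  expect_equal(sel$fm, cand$fm[best])
  expect_equal(sel$M, cand$M[best])
  expect_equal(sel$expected_entropy, exhaustive[best], tolerance = 1e-10)
  # by definition no candidate does better
  expect_true(all(sel$expected_entropy <= exhaustive + 1e-12))
})

test_that("a point-mass posterior yields zero gain and the tie-break picks the lowest pair", {
  g <- tiny_grid()
  g$mass <- rep(0, length(g$mass))
  g$mass[17] <- 1
  cand <- tibble::tibble(fm = c(2, 1, 1), M = c(0.2, 0.9, 0.3))
  sel <- select_stimulus(g, cand)
  expect_equal(sel$expected_entropy, 0, tolerance = 1e-10)
  expect_equal(c(sel$fm, sel$M), c(1, 0.3))   # lowest fm, then lowest M
  expect_error(select_stimulus(g, cand[0, ]), "empty")
})

test_that("expected entropy never exceeds the current entropy, for any candidate", {
  g <- tiny_grid()
  g <- update_posterior(g, list(fm = 1, M = 0.8, response_correct = TRUE))
  eng <- dichoptr:::qiocsf_engine(g, qiocsf_candidates(n_f = 5, n_M = 5))
  eh <- dichoptr:::expected_entropies(eng, g$mass)
  expect_true(all(eh <= posterior_entropy(g) + 1e-9))
})

test_that("sessions are deterministic and the fast path replays exactly", {
  obs <- standard_observer()
  g <- tiny_grid()
  cand <- tiny_candidates()
  f1 <- run_qiocsf_session(obs, n_trials = 12, seed = 3, grid = g,
                           candidates = cand)
  f2 <- run_qiocsf_session(obs, n_trials = 12, seed = 3, grid = g,
                           candidates = cand)
  expect_identical(f1$trials, f2$trials)
  expect_equal(f1$params, f2$params)

  # replay with the general operations and the same RNG stream
  cand_sorted <- dplyr::arrange(cand, fm, M)
  post <- g
  log <- NULL
  set.seed(3)
  for (i in 1:12) {
    sel <- select_stimulus(post, cand_sorted)
    ori <- sample(c(45L, 135L), 1)
    p_true <- prob_correct(sel$M, sel$fm, obs$iocsf_true, obs$lapse,
                           obs$psychometric_slope)
    correct <- stats::runif(1) < p_true
    post <- update_posterior(post, list(fm = sel$fm, M = sel$M,
                                        response_correct = correct))
    log <- rbind(log, data.frame(fm = sel$fm, M = sel$M,
                                 response_correct = correct))
  }
  expect_equal(f1$trials$fm, log$fm)
  expect_equal(f1$trials$M, log$M)
  expect_equal(f1$trials$response_correct, log$response_correct)
  expect_equal(f1$posterior$mass, post$mass, tolerance = 1e-9)
})

test_that("zero trials returns the prior mean and the log has n rows", {
  obs <- standard_observer()
  g <- tiny_grid()
  f0 <- run_qiocsf_session(obs, n_trials = 0, seed = 1, grid = g,
                           candidates = tiny_candidates())
  expect_equal(nrow(f0$trials), 0)
  expect_equal(f0$params, posterior_estimate(g))
  f5 <- run_qiocsf_session(obs, n_trials = 5, seed = 1, grid = g,
                           candidates = tiny_candidates())
  expect_equal(nrow(f5$trials), 5)
  expect_equal(f5$trials$trial_index, 1:5)
})

test_that("parameter bias shrinks as trials grow", {
  obs <- standard_observer()
  grid <- posterior_grid()
  cand <- qiocsf_candidates()
  eng <- dichoptr:::qiocsf_engine(grid, cand)
  err <- function(n_trials, n_sessions = 8) {
    e <- vapply(seq_len(n_sessions), function(s) {
      f <- run_qiocsf_session(obs, n_trials, seed = 100 + s, grid = grid,
                              candidates = cand, engine = eng)
      abs(log10(f$params$gamma_max) - 1)
    }, numeric(1))
    stats::median(e)
  }
  e25 <- err(25); e100 <- err(100); e400 <- err(400)
  expect_lt(e400, e25)
  expect_lt(e100, e25 + 0.02)
  expect_lt(e400, e100 + 0.02)
})

test_that("trial logs round-trip through CSV", {
  obs <- standard_observer()
  f <- run_qiocsf_session(obs, n_trials = 6, seed = 2, grid = tiny_grid(),
                          candidates = tiny_candidates())
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(f$trials, path)
  back <- read_trial_log(path)
  expect_equal(back$fm, f$trials$fm)
  expect_equal(back$response_correct, f$trials$response_correct)
})
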