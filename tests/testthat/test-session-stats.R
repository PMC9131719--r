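long_table <- function(Y) {
  tibble::tibble(subject = rep(rownames(Y), ncol(Y)),
                 condition = rep(colnames(Y), each = nrow(Y)),
                 value = as.vector(Y))
}

rand_table <- function(n, k, seed, integers = TRUE) {
  set.seed(seed)
  Y <- matrix(if (integers) sample(0:9, n * k, replace = TRUE)
              else stats::rnorm(n * k), n, k,
              dimnames = list(paste0("s", 1:n), paste0("c", 1:k)))
  Y
}

# classical sums-of-squares decomposition, written out from first principles
hand_rm_anova <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  ss_cond <- n * sum((colMeans(Y) - grand)^2)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  Fv <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  list(F = Fv, df1 = k - 1, df2 = (n - 1) * (k - 1),
       p = stats::pf(Fv, k - 1, (n - 1) * (k - 1), lower.tail = FALSE))
}

test_that("baseline normalisation subtracts per subject and inverts", {
  Y <- matrix(c(2, 5, 3, 1, 1, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("pre", "post0", "post10")))
  tab <- long_table(Y)
  ch <- normalize_to_baseline(tab, baseline = "pre")
  expect_equal(ch$value[ch$subject == "s1"], c(0, 3, 1))
  expect_equal(ch$value[ch$subject == "s2"], c(0, 0, 0))
  # re-adding the baseline recovers the original table
  base <- tab$value[tab$condition == "pre"][match(ch$subject,
            tab$subject[tab$condition == "pre"])]
  expect_equal(ch$value + base, tab$value)
  dropped <- normalize_to_baseline(tab, baseline = "pre",
                                   drop_baseline = TRUE)
  expect_false("pre" %in% dropped$condition)
  expect_error(normalize_to_baseline(tab, baseline = "nope"), "baseline")
})

test_that("one-way RM ANOVA agrees with hand-computed sums of squares", {
  # fixed 4 x 3 integer toy table
  Y <- matrix(c(3, 5, 4,
                7, 9, 9,
                2, 4, 3,
                6, 6, 8), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), c("a", "b", "c")))
  hand <- hand_rm_anova(Y)
  fit <- rm_anova_one_way(long_table(Y), sphericity = "never")
  td <- tidy(fit)
  expect_equal(td$statistic, hand$F, tolerance = 1e-12)
  expect_equal(td$df1, hand$df1)
  expect_equal(td$df2, hand$df2)
  expect_equal(td$p.value, hand$p, tolerance = 1e-12)
  # and on a batch of random 5 x 4 integer tables
  for (s in 1:20) {
    Y <- rand_table(5, 4, seed = s)
    hand <- hand_rm_anova(Y)
    td <- tidy(rm_anova_one_way(long_table(Y), sphericity = "never"))
    expect_equal(td$statistic, hand$F, tolerance = 1e-10)
    expect_equal(td$p.value, hand$p, tolerance = 1e-10)
  }
})

test_that("with two conditions F equals the squared paired t statistic", {
  Y <- rand_table(8, 2, seed = 3, integers = FALSE)
  td <- tidy(rm_anova_one_way(long_table(Y)))
  tt <- stats::t.test(Y[, 1], Y[, 2], paired = TRUE)
  expect_equal(td$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(td$df1, 1)
  expect_equal(td$df2, 7)
  expect_equal(td$p.value, tt$p.value, tolerance = 1e-10)
  expect_equal(td$epsilon, 1)          # epsilon is exactly 1 at k = 2
})

test_that("identical conditions give F = 0 and degenerate tables are flagged", {
  Y <- matrix(rep(stats::rnorm(6), 3), 6, 3,
              dimnames = list(paste0("s", 1:6), c("a", "b", "c")))
  td <- tidy(rm_anova_one_way(long_table(Y + 1e-30), sphericity = "never"))
  expect_true(td$degenerate || td$statistic == 0)
  # conditions equal per subject plus noise-free condition shift: F finite 0?
  Y2 <- rand_table(6, 3, seed = 1, integers = FALSE)
  Y2 <- Y2 - (Y2 - rowMeans(Y2))       # all conditions identical per subject
  td2 <- tidy(rm_anova_one_way(long_table(Y2)))
  expect_true(td2$degenerate)          # zero effect AND zero error variance
})

test_that("Greenhouse-Geisser epsilon stays in its bounds and is 1 under sphericity", {
  for (s in 1:10) {
    Y <- rand_table(8, 4, seed = 40 + s, integers = FALSE)
    td <- tidy(rm_anova_one_way(long_table(Y), sphericity = "always"))
    expect_gt(td$epsilon, 1 / 3)
    expect_lte(td$epsilon, 1)
    expect_equal(td$df1, td$epsilon * 3, tolerance = 1e-12)
    expect_equal(td$df2, td$epsilon * 21, tolerance = 1e-12)
  }
  # columns whitened to an identity sample covariance satisfy sphericity
  Y <- rand_table(12, 4, seed = 7, integers = FALSE)
  Yc <- sweep(Y, 2, colMeans(Y))
  W <- Yc %*% solve(chol(stats::cov(Y)))
  colnames(W) <- colnames(Y); rownames(W) <- rownames(Y)
  td <- tidy(rm_anova_one_way(long_table(W + 5), sphericity = "always"))
  expect_equal(td$epsilon, 1, tolerance = 1e-10)
})

test_that("one- and two-way results agree with car's repeated-measures machinery", {
  library(car)
  Y <- rand_table(10, 5, seed = 13, integers = FALSE)
  td <- tidy(rm_anova_one_way(long_table(Y), sphericity = "always"))
  mod <- stats::lm(Y ~ 1)
  id <- data.frame(cond = factor(colnames(Y), levels = colnames(Y)))
  # (car warns about its own Huynh-Feldt epsilon clamp; not under test here)
  s <- suppressWarnings(
    summary(car::Anova(mod, idata = id, idesign = ~cond, type = 3),
            multivariate = FALSE))
  ut <- s$univariate.tests
  expect_equal(td$statistic, ut["cond", "F value"], tolerance = 1e-8)
  expect_equal(td$epsilon, unname(s$pval.adjustments["cond", "GG eps"]),
               tolerance = 1e-8)
  expect_equal(td$p.value,
               unname(s$pval.adjustments["cond", "Pr(>F[GG])"]),
               tolerance = 1e-8)
  expect_equal(td$mauchly_W, unname(s$sphericity.tests["cond",
               "Test statistic"]), tolerance = 1e-8)
  # second-order Box term conventions differ slightly (stats uses the
  # original variable count where Box's expansion has the contrast
  # dimension); W is exact, p agrees to ~1e-3
  expect_equal(td$mauchly_p, unname(s$sphericity.tests["cond", "p-value"]),
               tolerance = 2e-3)

  # two-way fully-within design against car, per effect
  set.seed(99)
  a <- 3; b <- 4; n <- 9
  Y2 <- matrix(stats::rnorm(n * a * b), n, a * b)
  lv <- expand.grid(t = paste0("t", 1:a), f = paste0("f", 1:b))
  df2 <- tibble::tibble(
    subject = rep(paste0("s", 1:n), a * b),
    time = rep(as.character(lv$t), each = n),
    frequency = rep(as.character(lv$f), each = n),
    value = as.vector(Y2))
  td2 <- tidy(rm_anova_two_way(df2, sphericity = "always"))
  mod2 <- stats::lm(Y2 ~ 1)
  s2 <- suppressWarnings(
    summary(car::Anova(mod2, idata = lv, idesign = ~t * f, type = 3),
            multivariate = FALSE))
  ut2 <- s2$univariate.tests
  adj <- s2$pval.adjustments
  expect_equal(td2$statistic[td2$effect == "time"], ut2["t", "F value"],
               tolerance = 1e-8)
  expect_equal(td2$statistic[td2$effect == "frequency"],
               ut2["f", "F value"], tolerance = 1e-8)
  expect_equal(td2$statistic[td2$effect == "time:frequency"],
               ut2["t:f", "F value"], tolerance = 1e-8)
  expect_equal(td2$epsilon[td2$effect == "time:frequency"],
               unname(adj["t:f", "GG eps"]), tolerance = 1e-8)
  expect_equal(td2$p.value[td2$effect == "time:frequency"],
               unname(adj["t:f", "Pr(>F[GG])"]), tolerance = 1e-8)
})

test_that("a single-level second factor reduces the two-way to the one-way analysis", {
  Y <- rand_table(6, 4, seed = 21, integers = FALSE)
  df <- long_table(Y)
  df$time <- df$condition
  df$frequency <- "f1"
  td2 <- tidy(rm_anova_two_way(df, sphericity = "never"))
  td1 <- tidy(rm_anova_one_way(long_table(Y), sphericity = "never"))
  expect_equal(nrow(td2), 1)
  expect_equal(td2$statistic, td1$statistic, tolerance = 1e-12)
  expect_equal(td2$p.value, td1$p.value, tolerance = 1e-12)
})

test_that("two-way interaction type-I error sits at alpha under the null", {
  set.seed(2024)
  rej <- vapply(1:500, function(r) {
    n <- 8; a <- 3; b <- 3
    lv <- expand.grid(t = paste0("t", 1:a), f = paste0("f", 1:b))
    df <- tibble::tibble(
      subject = rep(paste0("s", 1:n), a * b),
      time = rep(as.character(lv$t), each = n),
      frequency = rep(as.character(lv$f), each = n),
      value = rep(stats::rnorm(n), a * b) + stats::rnorm(n * a * b))
    td <- tidy(rm_anova_two_way(df))
    td$p.value[td$effect == "time:frequency"] < 0.05
  }, logical(1))
  ci <- 2.576 * sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(mean(rej) - 0.05), ci)
})

test_that("additive data show main effects but no interaction", {
  set.seed(5)
  n <- 10; a <- 3; b <- 3
  lv <- expand.grid(t = 1:a, f = 1:b)
  df <- tibble::tibble(
    subject = rep(paste0("s", 1:n), a * b),
    time = rep(paste0("t", lv$t), each = n),
    frequency = rep(paste0("f", lv$f), each = n),
    value = rep(stats::rnorm(n), a * b) +
      rep(lv$t, each = n) * 1.5 + rep(lv$f, each = n) * 1.0 +
      stats::rnorm(n * a * b, 0, 0.5))
  td <- tidy(rm_anova_two_way(df))
  expect_lt(td$p.value[td$effect == "time"], 1e-4)
  expect_lt(td$p.value[td$effect == "frequency"], 1e-4)
  # no generated interaction: its p is a draw from ~Uniform(0,1)
  expect_gt(td$p.value[td$effect == "time:frequency"], 0.01)
})

test_that("the BIC Bayes factor follows its defining algebra", {
  Y <- rand_table(8, 3, seed = 31, integers = FALSE)
  tab <- long_table(Y)
  bf <- bf01_bic(tab)
  b0 <- stats::BIC(stats::lm(value ~ subject, data = tab))
  b1 <- stats::BIC(stats::lm(value ~ subject + condition, data = tab))
  expect_equal(bf$bf01, exp((b1 - b0) / 2), tolerance = 1e-12)
  # identical models: BF01 = 1 by construction
  expect_equal(bf01_bic(tab, value ~ subject, value ~ subject)$bf01, 1)
  # a BIC gap of 2 log 10 sits exactly on the substantial/strong boundary
  expect_equal(exp(2 * log(10) / 2), 10)
  expect_equal(dichoptr:::bf01_band(10), "strong")
  expect_equal(dichoptr:::bf01_band(9.99), "substantial")
  expect_error(bf01_bic(tab, value ~ condition, value ~ subject),
               "nested")
})

test_that("noncentral-t power matches an independent quadrature oracle", {
  # power as a chi-square mixture of normal tail probabilities:
  # P(T > c) = E_V[ P(Z > c * sqrt(V / df) - ncp) ], V ~ chi^2(df)
  oracle_power <- function(mean, sd, n, alpha, tail) {
    df <- n - 1
    ncp <- mean / sd * sqrt(n)
    tailp <- function(crit) stats::integrate(function(v)
      stats::dchisq(v, df) *
        stats::pnorm(crit * sqrt(v / df) - ncp, lower.tail = FALSE),
      0, Inf, rel.tol = 1e-10)$value
    if (tail == "one") tailp(stats::qt(1 - alpha, df))
    else {
      crit <- stats::qt(1 - alpha / 2, df)
      tailp(crit) + (1 - tailp(-crit))
    }
  }
  cases <- list(list(1.39, 1.24, 7, "one"), list(1.39, 1.24, 6, "one"),
                list(19.2, 7.0, 3, "one"), list(6.3, 3.3, 5, "two"))
  for (cs in cases) {
    spec <- power_spec(cs[[1]], cs[[2]], tail = cs[[4]])
    expect_equal(power_one_sample_t(spec, cs[[3]]),
                 oracle_power(cs[[1]], cs[[2]], cs[[3]], 0.05, cs[[4]]),
                 tolerance = 1e-7)
  }
  # null effect, one tail: power equals alpha
  expect_equal(power_one_sample_t(power_spec(1e-12, 1), 10), 0.05,
               tolerance = 1e-6)
})

test_that("power grows with n and with the standardised effect", {
  spec <- power_spec(1.39, 1.24)
  pw <- power_one_sample_t(spec, 2:15)
  expect_true(all(diff(pw) > 0))
  effects <- seq(0.2, 2, by = 0.2)
  pw2 <- vapply(effects, function(d)
    power_one_sample_t(power_spec(d, 1), 8), numeric(1))
  expect_true(all(diff(pw2) > 0))
})

test_that("minimum sample sizes scan correctly", {
  expect_equal(min_sample_size_t(power_spec(100, 1)), 2)
  expect_error(min_sample_size_t(power_spec(0, 1)), "zero effect")
  # consistency: the returned n meets the target, n - 1 does not
  spec <- power_spec(0.9, 1.1)
  n <- min_sample_size_t(spec)
  expect_gte(power_one_sample_t(spec, n), 0.8)
  expect_lt(power_one_sample_t(spec, n - 1), 0.8)
})

test_that("session analysis wires the pieces together", {
  coh <- make_cohort(8, "null", seed = 77)
  ds <- simulate_experiment(coh, experiment_protocol(measures = "phase"))
  an <- analyze_sessions(ds, "phase")
  g <- glance(an)
  expect_equal(an$anova$n, 8)
  expect_true(g$p.value >= 0 && g$p.value <= 1)
  expect_true(is.finite(g$bf01))
  # post contrast drops the baseline: 5 conditions
  expect_equal(length(unique(an$changes$condition)), 5)
  all6 <- analyze_sessions(ds, "phase", contrast = "all")
  expect_equal(length(unique(all6$changes$condition)), 6)
})
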