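test_that("Kaplan-Meier matches the hand product-limit and KM axioms", {
  # all censored -> S(t) = 1 everywhere
  km0 <- kaplan_meier(c(5, 10, 15), c(0, 0, 0))
  expect_equal(lc_rate_at(km0, 0), 1)
  expect_equal(lc_rate_at(km0, 100), 1)

  # times 1,2,3 all events: S = 2/3, 1/3, 0 after each step
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(lc_rate_at(km, 0), 1)
  expect_equal(lc_rate_at(km, 1.5), 2 / 3)
  expect_equal(lc_rate_at(km, 3), 0)
  expect_equal(lc_rate_at(km, 99), 0) # beyond the last event

  # without censoring KM equals the empirical survival proportion
  set.seed(8)
  t <- rexp(200, 0.1)
  km2 <- kaplan_meier(t, rep(1, 200))
  expect_equal(lc_rate_at(km2, 12), mean(t > 12))
  # non-increasing and right-continuous step function
  expect_true(all(diff(km2$surv) <= 0))
  expect_equal(km2$fn(km2$time[5]), km2$surv[5])
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), class = "ctv_survival_error")
})

test_that("log-rank equals the hand-computed observed-minus-expected form", {
  # 6-subject worked example, two groups, one censoring
  time <- c(1, 2, 3, 4, 4, 5)
  event <- c(1, 1, 0, 1, 1, 1)
  group <- c(0, 1, 0, 1, 0, 1)
  # oracle: loop over distinct event times accumulating O-E and variance
  o_minus_e <- 0; v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & group == 1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oracle_chisq <- o_minus_e^2 / v
  lr <- log_rank(time, event, group)
  expect_equal(lr$chisq, oracle_chisq, tolerance = 1e-12)
  expect_equal(lr$p_value, pchisq(oracle_chisq, 1, lower.tail = FALSE))
  # label-swap invariance
  expect_equal(log_rank(time, event, 1 - group)$chisq, lr$chisq)
  # identical groups: statistic ~ 0, p ~ 1
  lr0 <- log_rank(rep(time, 2), rep(event, 2), rep(c(0, 1), each = 6))
  expect_lt(lr0$chisq, 1e-10)
  expect_gt(lr0$p_value, 0.999)
  expect_error(log_rank(time, rep(0, 6), group), class = "ctv_survival_error")
})

test_that("log-rank chi-square p agrees with a permutation null", {
  set.seed(14)
  n <- 60
  g <- rep(c(0, 1), each = n / 2)
  t <- rexp(n, 0.04 * exp(0.9 * g))
  ev <- rep(1, n)
  lr <- log_rank(t, ev, g)
  perm <- replicate(2000, {
    gp <- sample(g)
    log_rank(t, ev, gp)$chisq
  })
  p_perm <- mean(perm >= lr$chisq)
  expect_lt(abs(p_perm - lr$p_value), 0.02)
})

test_that("Cox on a binary covariate maximizes the Breslow partial likelihood", {
  time <- c(2, 3, 3, 5, 6, 7, 8, 9)
  event <- c(1, 1, 1, 0, 1, 1, 0, 1)
  g <- c(1, 0, 1, 1, 0, 1, 0, 0)
  breslow_ll <- function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + beta * g[i] - log(sum(exp(beta * g[risk])))
    }
    ll
  }
  opt <- stats::optimize(breslow_ll, c(-5, 5), maximum = TRUE, tol = 1e-9)
  fit <- cox_univariate_binary(time, event, g)
  expect_equal(fit$beta, opt$maximum, tolerance = 1e-4)
  expect_equal(fit$hr, exp(opt$maximum), tolerance = 1e-4)
  expect_true(fit$ci_lower < fit$hr && fit$hr < fit$ci_upper)
})

test_that("Cox recovers null and planted hazard ratios on exponential data", {
  set.seed(20)
  n <- 1000
  g <- rbinom(n, 1, 0.5)
  # null: no effect
  t0 <- rexp(n, 0.05)
  fit0 <- cox_univariate_binary(t0, rep(1, n), g)
  expect_lt(abs(fit0$beta), 3 * fit0$se)
  # planted HR 2 with light censoring
  t1 <- rexp(n, 0.03 * exp(log(2) * g))
  cens <- rexp(n, 0.005)
  fit1 <- cox_univariate_binary(pmin(t1, cens), as.numeric(t1 <= cens), g)
  expect_lt(abs(fit1$beta - log(2)), 3 * fit1$se)
  expect_error(cox_univariate_binary(t0, rep(1, n), rep(1, n)),
               class = "ctv_survival_error")
})

test_that("2x2 statistics follow the closed forms and the exact-test branch", {
  sym <- contingency_2x2(10, 10, 10, 10)
  expect_equal(sym$odds_ratio, 1)
  # printed tumor-diameter table: OR = (65*63)/(31*21)
  tab <- contingency_2x2(65, 31, 21, 63)
  expect_equal(tab$odds_ratio, 65 * 63 / (31 * 21))
  expect_equal(tab$test, "chisq")
  expect_equal(tab$p_value,
               chisq.test(matrix(c(65, 31, 21, 63), 2, byrow = TRUE))$p.value)
  woolf_se <- sqrt(1 / 65 + 1 / 31 + 1 / 21 + 1 / 63)
  expect_equal(tab$ci_lower, exp(log(tab$odds_ratio) - 1.96 * woolf_se))
  # small expected cell -> Fisher's exact test
  small <- contingency_2x2(3, 1, 2, 4)
  expect_equal(small$test, "fisher")
  expect_equal(small$p_value,
               fisher.test(matrix(c(3, 1, 2, 4), 2, byrow = TRUE))$p.value)
  expect_error(contingency_2x2(0, 0, 5, 5), class = "ctv_contingency_error")
  expect_error(contingency_2x2(-1, 2, 3, 4), class = "ctv_contingency_error")
})

test_that("the local-control contrast bundles KM, log-rank and Cox coherently", {
  set.seed(9)
  n <- 400
  diam <- runif(n, 2, 8)
  g <- diam >= 5
  t <- rexp(n, 0.02 * exp(log(1.635) * g))
  cens <- rexp(n, 0.01)
  res <- local_control_contrast(pmin(t, cens), as.numeric(t <= cens),
                                ifelse(g, ">=5", "<5"), horizon_months = 36)
  expect_named(res$lc_rate, c("<5", ">=5"))
  expect_gt(res$lc_rate["<5"], res$lc_rate[">=5"])
  expect_true(res$cox$hr > 1)
})
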