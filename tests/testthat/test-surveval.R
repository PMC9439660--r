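test_that("Kaplan-Meier curves match hand product-limit results", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(1, 2 / 3, 1 / 3, 0))
  expect_equal(km$time, c(0, 1, 2, 3))

  km0 <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  # moving a censoring time that already falls after the last event
  # leaves the curve unchanged
  km_a <- km_curve(c(1, 2, 3, 4), c(1, 1, 1, 0))
  km_b <- km_curve(c(1, 2, 3, 10), c(1, 1, 1, 0))
  expect_equal(histoscore:::km_surv_at(km_b, c(1, 2, 3)),
               histoscore:::km_surv_at(km_a, c(1, 2, 3)))

  # with full event data the KM is the empirical survival function
  set.seed(41)
  tt <- rexp(50)
  km_f <- km_curve(tt, rep(1, 50))
  for (q in c(0.2, 0.5, 0.9))
    expect_equal(histoscore:::km_surv_at(km_f, quantile(tt, q)),
                 mean(tt > quantile(tt, q)))

  expect_error(km_curve(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank matches a hand O-E/V tally and its symmetries", {
  time <- c(2, 4, 5, 7, 8, 11, 12, 15)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  group <- c("a", "b", "a", "b", "a", "b", "a", "b")
  lr <- logrank_test(time, event, group)
  expect_equal(lr$statistic, logrank_hand(time, event, group),
               tolerance = 1e-6)

  swapped <- logrank_test(time, event, ifelse(group == "a", "b", "a"))
  expect_equal(swapped$statistic, lr$statistic, tolerance = 1e-12)

  dup <- logrank_test(rep(time, 2), rep(event, 2),
                      rep(c("a", "b"), each = 8))
  # identical groups (duplicated data split by copy): statistic 0
  expect_equal(dup$statistic, 0, tolerance = 1e-12)
  expect_equal(dup$p_value, 1, tolerance = 1e-9)

  expect_error(logrank_test(time, event, rep("a", 8)), "2")
})

test_that("Cox regression matches a brute-force likelihood oracle", {
  set.seed(42)
  n <- 20
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, exp(0.9 * x))
  fit <- cox_fit(tt, rep(1, n), data.frame(x = x), mode = "multi")
  oracle <- cox_newton_oracle(tt, rep(1, n), matrix(x, ncol = 1))
  expect_equal(fit$table$beta, oracle, tolerance = 1e-5)
  expect_true(fit$table$lower <= fit$table$hr &
                fit$table$hr <= fit$table$upper)

  # duplicating every subject leaves the HR essentially unchanged (exact
  # under Breslow ties; Efron's correction for the induced ties perturbs
  # it slightly)
  fit2 <- cox_fit(rep(tt, 2), rep(1, 2 * n), data.frame(x = rep(x, 2)))
  expect_equal(fit2$table$hr, fit$table$hr, tolerance = 0.03)

  expect_error(cox_fit(tt, rep(0, n), data.frame(x = x)), "few events")
})

test_that("Cox Wald intervals achieve nominal coverage under the null", {
  covered <- 0
  for (r in 1:200) {
    set.seed(800 + r)
    n <- 150
    x <- rnorm(n)
    tt <- rexp(n, 0.2)
    cc <- runif(n, 0, quantile(tt, 0.9))
    f <- cox_fit(pmin(tt, cc), as.integer(tt <= cc), data.frame(x = x))
    if (f$table$lower <= 1 && 1 <= f$table$upper) covered <- covered + 1
  }
  expect_gt(covered / 200, 0.90)
  expect_lt(covered / 200, 0.99)
})

test_that("Harrell's C follows the risk-orientation convention exactly", {
  set.seed(43)
  tt <- sort(rexp(30))
  score <- rank(tt)    # higher score for longer survival = anti-risk
  expect_equal(harrell_c(tt, rep(1, 30), score)$c_index, 0)
  expect_equal(harrell_c(tt, rep(1, 30), -score)$c_index, 1)

  # exhaustive pair enumeration oracle at n = 6 with censoring and ties
  t6 <- c(2, 5, 5, 7, 9, 12)
  e6 <- c(1, 1, 0, 1, 0, 1)
  s6 <- c(3.1, 2.0, 2.0, 1.4, 0.9, 0.5)
  expect_equal(harrell_c(t6, e6, s6)$c_index, cstat_enum(t6, e6, s6))

  # complement identity without score ties
  set.seed(44)
  tt2 <- rexp(40); ev2 <- rbinom(40, 1, 0.7); sc2 <- rnorm(40)
  expect_equal(harrell_c(tt2, ev2, sc2)$c_index +
                 harrell_c(tt2, ev2, -sc2)$c_index, 1)

  # random score: C ~ 0.5
  set.seed(45)
  n <- 1000
  tt3 <- rexp(n); cc3 <- runif(n, 0, quantile(tt3, 0.9))
  cr <- harrell_c(pmin(tt3, cc3), as.integer(tt3 <= cc3), rnorm(n))$c_index
  expect_lt(abs(cr - 0.5), 0.03)

  expect_error(harrell_c(c(1, 2), c(0, 0), c(1, 2)), "comparable")
})

test_that("time-dependent AUC reduces to the plain ROC AUC without censoring", {
  set.seed(46)
  n <- 400
  lp <- rnorm(n)
  tt <- rexp(n, exp(lp))
  horizon <- median(tt)
  auc <- td_roc_auc(tt, rep(1, n), lp, horizon)
  expect_equal(auc, plain_auc(as.integer(tt <= horizon), lp),
               tolerance = 1e-10)

  # perfectly separating score
  y <- as.integer(tt <= horizon)
  expect_equal(td_roc_auc(tt, rep(1, n), y * 10, horizon), 1)

  # random score ~ 0.5 under censoring
  set.seed(47)
  n <- 800
  tt2 <- rexp(n, 0.2); cc2 <- runif(n, 0, quantile(tt2, 0.9))
  a <- td_roc_auc(pmin(tt2, cc2), as.integer(tt2 <= cc2), rnorm(n),
                  median(tt2))
  expect_lt(abs(a - 0.5), 0.04)

  expect_error(td_roc_auc(c(5, 6), c(1, 1), c(1, 2), 1), "no cases")
})

test_that("td-AUC and Harrell's C agree for exponential survival without censoring", {
  # the two coincide in the weak-effect regime, where the cumulative
  # AUC is nearly constant over horizons
  set.seed(48)
  n <- 2000
  lp <- rnorm(n, 0, 0.25)
  tt <- rexp(n, exp(lp))
  cc <- harrell_c(tt, rep(1, n), lp)$c_index
  aa <- td_roc_auc(tt, rep(1, n), lp, median(tt))
  expect_lt(abs(cc - aa), 0.03)
})

test_that("calibration recovers the generating risk within tolerance", {
  set.seed(49)
  n <- 1000
  lp <- rnorm(n, 0, 0.8)
  scale <- 60
  tt <- scale * (-log(runif(n)) * exp(-lp))
  cc <- runif(n, 0, 3 * scale)
  time <- pmin(tt, cc); event <- as.integer(tt <= cc)
  horizon <- 24
  pred <- 1 - exp(-(horizon / scale) * exp(lp))   # true model risk
  cal <- calibration_curve(pred, time, event, horizon)
  expect_lte(max(abs(cal$mean_predicted - cal$observed)), 0.07)
  expect_true(all(diff(cal$observed) > -0.05))   # monotone up to noise

  # constant prediction: a single effective bin matching the marginal KM
  expect_warning(cal1 <- calibration_curve(rep(mean(pred), n), time, event,
                                           horizon), "merged")
  km <- km_curve(time, event)
  expect_equal(cal1$observed[1], 1 - histoscore:::km_surv_at(km, horizon),
               tolerance = 1e-12)
  expect_error(calibration_curve(pred * 3, time, event, horizon), "0, 1")
})

test_that("continuous NRI counts reclassification like a hand tally", {
  # identical scores: exactly zero
  set.seed(50)
  tt <- rexp(100); ev <- rbinom(100, 1, 0.8)
  s <- rnorm(100)
  z <- nri(s, s, tt, ev, median(tt), n_boot = 0)
  expect_equal(z$nri, 0)

  # hand-counted 10-subject set without censoring
  t10 <- 1:10
  e10 <- rep(1, 10)
  old <- c(5, 4, 6, 2, 7, 1, 3, 8, 9, 10)
  new <- c(6, 3, 7, 1, 8, 2, 3, 9, 8, 11)
  horizon <- 5.5
  up <- new > old; dn <- new < old
  is_case <- t10 <= horizon
  hand <- (sum(up & is_case) - sum(dn & is_case)) / sum(is_case) +
    (sum(dn & !is_case) - sum(up & !is_case)) / sum(!is_case)
  got <- nri(new, old, t10, e10, horizon, n_boot = 0)
  expect_equal(got$nri, hand, tolerance = 1e-12)

  # informative new score vs noise: positive with CI excluding 0
  co <- default_cohort(600, seed = 55)
  noise <- with_seed(56, rnorm(600))
  r <- nri(co$lp, noise, co$time, co$event, median(co$time),
           n_boot = 400, seed = 57)
  expect_gt(r$nri, 0)
  expect_gt(r$lower, 0)

  expect_error(nri(s, s, tt, ev, max(tt) + 1, n_boot = 0), "follow-up")
})

test_that("baseline-risk predictions are monotone in the linear predictor", {
  set.seed(58)
  n <- 300
  lp <- rnorm(n)
  tt <- rexp(n, 0.05 * exp(lp))
  cc <- runif(n, 0, quantile(tt, 0.9))
  risk <- cox_baseline_risk(pmin(tt, cc), as.integer(tt <= cc), lp,
                            median(tt))
  expect_true(all(risk >= 0 & risk <= 1))
  o <- order(lp)
  expect_true(all(diff(risk[o]) >= 0))
})
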