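test_that("mann_whitney orientation, exactness and enumeration oracle", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_true(mw$exact)
  # enumeration oracle: U = number of (a, b) pairs with a > b (+ ties/2)
  set.seed(3)
  for (rep in 1:20) {
    a <- sample(1:50, 5)
    b <- sample(1:50, 6)
    u_oracle <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    expect_equal(mann_whitney(a, b)$U, u_oracle)
  }
  # identical samples: p = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(mann_whitney(numeric(0), 1), "empty")
  # agreement with the reference implementation on large samples
  set.seed(4)
  a <- rnorm(40); b <- rnorm(45, 0.5)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  got <- mann_whitney(a, b)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("mann_whitney has power against a 1-sd shift", {
  rej <- vapply(1:100, function(i) {
    set.seed(5000 + i)
    mann_whitney(rnorm(100, 1), rnorm(100))$p < 0.01
  }, logical(1))
  expect_gte(mean(rej), 0.95)
})

test_that("roc_auc rank formula, flips and U identity", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(3, 1, 2, 0), c(1, 1, 0, 0)), 0.75)
  set.seed(6)
  s <- rnorm(60); l <- runif(60) < 0.4
  expect_equal(roc_auc(s, !l), 1 - roc_auc(s, l))
  u <- mann_whitney(s[l], s[!l])$U
  expect_equal(roc_auc(s, l), u / (sum(l) * sum(!l)), tolerance = 1e-12)
  expect_error(roc_auc(s, rep(TRUE, 60)), "both classes")
})

test_that("logrank matches the two-subject hand example and null", {
  lr <- logrank_test(c(1, 2), c(1, 1), c("g1", "g2"))
  expect_equal(lr$chi2, 1.0)
  expect_equal(unname(lr$E), c(0.5, 1.5))
  expect_equal(unname(lr$O), c(1, 1))
  expect_equal(sum(lr$O), 2)

  set.seed(7)
  t1 <- rexp(50); t2 <- t1  # identical groups (duplicated times)
  lr2 <- logrank_test(c(t1, t2), rep(1, 100), rep(c("a", "b"), each = 50))
  expect_lt(lr2$chi2, 1e-10)
  expect_error(logrank_test(c(1, 2), c(0, 1), c("a", "b")), "event")
})

test_that("log-rank O totals conserve events", {
  set.seed(8)
  tab <- simulate_survival(80, log_hr = 0.4, censor_rate = 0.3, seed = 11)
  grp <- tab$biomarker > 0
  lr <- logrank_test(tab$time, tab$event, grp)
  expect_equal(sum(lr$O), sum(tab$event), tolerance = 1e-12)
})

test_that("hazard_ratio hand example and cox agreement", {
  hr <- hazard_ratio(c(1, 2), c(1, 1), c("g1", "g2"))
  expect_equal(hr$hr, 3.0)
  set.seed(9)
  tab <- simulate_survival(400, log_hr = 0.8, censor_rate = 0.2, seed = 12)
  grp <- factor(ifelse(tab$biomarker > 0, "high", "low"),
                levels = c("high", "low"))
  pike <- hazard_ratio(tab$time, tab$event, grp)
  cox <- hazard_ratio(tab$time, tab$event, grp, method = "cox")
  expect_gt(pike$hr, 1)
  expect_lt(abs(log(pike$hr) - log(cox$hr)), 0.25)
  expect_true(pike$ci[1] < pike$hr && pike$hr < pike$ci[2])
  # identical groups: HR near 1
  t1 <- rexp(50)
  hr1 <- hazard_ratio(c(t1, t1), rep(1, 100), rep(c("a", "b"), each = 50))
  expect_equal(hr1$hr, 1, tolerance = 1e-8)
})

test_that("cox newton solver agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(10)
  tab <- simulate_survival(300, log_hr = 0.6, censor_rate = 0.25, seed = 13)
  fit <- cscniche:::cox_newton(tab$time, tab$event, tab$biomarker)
  ref <- survival::coxph(survival::Surv(tab$time, tab$event) ~
                           tab$biomarker, ties = "breslow")
  expect_equal(fit$beta, unname(stats::coef(ref)), tolerance = 1e-6)
  expect_equal(fit$se, unname(sqrt(stats::vcov(ref)[1, 1])),
               tolerance = 1e-6)
})

test_that("maxstat finds a planted separator within the window", {
  set.seed(14)
  n <- 120
  x <- runif(n)
  # hazard jumps at x = 0.6
  rate <- ifelse(x > 0.6, 0.3, 0.05)
  tab <- data.frame(time = rexp(n, rate), event = 1, biomarker = x)
  ms <- maxstat_cutoff(tab)
  step <- max(diff(sort(unique(x))))
  expect_lt(abs(ms$cutoff - 0.6), 0.08)
  qs <- quantile(x, c(0.1, 0.9))
  expect_true(all(ms$candidates$cutpoint >= qs[1] &
                    ms$candidates$cutpoint <= qs[2]))
  expect_false(ms$p_selection_adjusted)
  expect_error(maxstat_cutoff(data.frame(time = rexp(30), event = 1,
                                         biomarker = rep(2, 30))),
               "identical")
  expect_error(maxstat_cutoff(tab[1:10, ]), "20 subjects")
})

test_that("statistics are invariant to subject ordering", {
  set.seed(15)
  tab <- simulate_survival(60, log_hr = 0.5, censor_rate = 0.2, seed = 16)
  grp <- tab$biomarker > 0
  perm <- sample(nrow(tab))
  lr1 <- logrank_test(tab$time, tab$event, grp)
  lr2 <- logrank_test(tab$time[perm], tab$event[perm], grp[perm])
  expect_equal(lr1$chi2, lr2$chi2)
  expect_equal(roc_auc(tab$biomarker, tab$event),
               roc_auc(tab$biomarker[perm], tab$event[perm]))
  ms1 <- maxstat_cutoff(tab)
  ms2 <- maxstat_cutoff(tab[perm, ])
  expect_equal(ms1$cutoff, ms2$cutoff)
})
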