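# Enumeration oracle for Fisher's exact test: sum the probabilities of
# all tables with the observed margins that are no more likely than the
# observed one.
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  sum(probs[probs <= dhyper(x_obs, m, n, k) * (1 + 1e-7)])
}

test_that("Pearson chi-square matches the uncorrected statistic", {
  prop <- rbind(c(20, 10), c(40, 20))       # perfectly proportional
  res <- pearson_chi2(prop)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  expect_equal(res$df, 1)

  # invariance under row and column permutation
  tab <- rbind(c(74, 60), c(73, 33))
  res1 <- pearson_chi2(tab)
  expect_equal(pearson_chi2(tab[2:1, ])$chi2, res1$chi2)
  expect_equal(pearson_chi2(tab[, 2:1])$chi2, res1$chi2)

  expect_error(pearson_chi2(rbind(c(0, 0), c(1, 2))), "zero row")
})

test_that("Fisher exact P agrees with hypergeometric enumeration", {
  tabs <- list(rbind(c(1, 9), c(11, 3)),
               rbind(c(5, 5), c(5, 5)),
               rbind(c(2, 7), c(8, 2)))
  for (tab in tabs) {
    expect_equal(fisher_exact(tab), fisher_enum_p(tab), tolerance = 1e-9)
    expect_equal(fisher_exact(t(tab)), fisher_exact(tab), tolerance = 1e-12)
  }
  expect_equal(fisher_exact(rbind(c(5, 5), c(5, 5))), 1)
  expect_error(fisher_exact(matrix(1, 2, 3)), "2 x 2")
})

test_that("association_test falls back to Fisher on sparse 2x2 tables", {
  sparse <- rbind(c(1, 9), c(11, 1))
  expect_identical(association_test(sparse)$method, "fisher")
  dense <- rbind(c(74, 60), c(73, 33))
  expect_identical(association_test(dense)$method, "pearson")
})

test_that("Kaplan-Meier matches the hand-computed product limit", {
  # all events at distinct times: S drops by 1/n at each
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$table$surv, c(2 / 3, 1 / 3, 0))

  # all censored: S stays at 1
  km2 <- km_estimate(c(5, 7, 9), c(0, 0, 0))
  expect_true(all(km2$table$surv == 1))

  # mixed 10-subject fixture; censoring at an event time counted after
  time <- c(1, 2, 2, 3, 4, 5, 6, 7, 8, 10)
  event <- c(1, 1, 0, 1, 0, 1, 0, 0, 1, 0)
  km3 <- km_estimate(time, event)
  ev <- km3$table[km3$table$n_event > 0, ]
  expect_equal(ev$time, c(1, 2, 3, 5, 8))
  expect_equal(ev$surv,
               c(0.9, 0.8, 0.8 * 6 / 7, 0.8 * 6 / 7 * 4 / 5,
                 0.8 * 6 / 7 * 4 / 5 * 1 / 2),
               tolerance = 1e-12)
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(3)
  time <- rexp(40, 0.1)
  km <- km_estimate(time, rep(1, 40))
  emp <- vapply(km$table$time, function(t) mean(time > t), numeric(1))
  expect_equal(km$table$surv, emp, tolerance = 1e-12)
})

test_that("log-rank test matches the direct hypergeometric formula", {
  set.seed(8)
  n <- 60
  g <- rep(c("A", "B"), each = n / 2)
  time <- rexp(n, 0.02 * exp(0.7 * (g == "B")))
  event <- as.integer(time <= 50); time <- pmin(time, 50)

  # direct evaluation: O - E and hypergeometric variance per event time
  ut <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    at <- time >= t
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == "A")
    n1 <- sum(at & g == "A"); nt <- sum(at)
    O <- O + d1
    E <- E + d * n1 / nt
    if (nt > 1) V <- V + d * (n1 / nt) * (1 - n1 / nt) * (nt - d) / (nt - 1)
  }
  chi2_direct <- (O - E)^2 / V
  res <- logrank_test(time, event, g)
  expect_equal(res$chi2, chi2_direct, tolerance = 1e-10)
  expect_equal(res$df, 1)

  # identical groups: chi2 = 0, p = 1
  same <- logrank_test(rep(time, 2), rep(event, 2),
                       rep(c("x", "y"), each = n))
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  expect_error(logrank_test(time, rep(0, n), g), "zero events")
})

test_that("log-rank chi2 is invariant under group relabeling", {
  set.seed(9)
  n <- 90
  g <- sample(c("a", "b", "c"), n, replace = TRUE)
  time <- rexp(n, 0.03)
  event <- as.integer(time <= 40); time <- pmin(time, 40)
  r1 <- logrank_test(time, event, g)
  relab <- c(a = "z", b = "x", c = "y")[g]
  r2 <- logrank_test(time, event, relab)
  expect_equal(r1$chi2, r2$chi2, tolerance = 1e-12)
  expect_equal(r1$df, 2)
})

test_that("Cox fit is unbiased on null data and flags zero variance", {
  set.seed(10)
  n <- 1000
  d <- data.frame(x = factor(sample(c("lo", "hi"), n, TRUE)),
                  z = factor(rep("only", n)),
                  time_months = rexp(n, 0.02), event = 1L)
  expect_warning(m <- cox_fit(d, c("x", "z")), "zero-variance")
  expect_lt(abs(m$coefficients$beta[m$coefficients$level == "hi"]), 0.1)
  expect_false("z" %in% m$covariates)
})

test_that("selection procedures keep signal and drop noise", {
  coh <- cohort_with_group(800, seed = 15)
  set.seed(15)
  coh$noise <- factor(sample(c("u", "v"), 800, TRUE))
  covs <- c("n_status", "grade", "noise")
  fw <- cox_fit(coh, covs, selection = "forward")
  bw <- cox_fit(coh, covs, selection = "backward")
  expect_true(all(c("n_status", "grade") %in% fw$covariates))
  expect_false("noise" %in% fw$covariates)
  expect_false("noise" %in% bw$covariates)
})

test_that("enter-selection univariate fit reproduces the forest-plot HR", {
  coh <- cohort_with_group(400, seed = 16)
  m <- cox_fit(coh, "tsr_group", selection = "enter")
  hr_fit <- m$coefficients$hr[m$coefficients$level == "stroma-low"]
  coh$all <- factor("all")
  fr <- subgroup_forest(coh, "all", exposure = "tsr_group")
  expect_equal(fr$hr[1], hr_fit, tolerance = 1e-8)

  # duplicated stratum: identical rows
  coh2 <- rbind(coh, coh)
  coh2$strat <- factor(rep(c("s1", "s2"), each = nrow(coh)))
  fr2 <- subgroup_forest(coh2, "strat", exposure = "tsr_group")
  expect_equal(fr2$hr[1], fr2$hr[2], tolerance = 1e-10)
})

test_that("strata without events are reported as undefined", {
  coh <- cohort_with_group(100, seed = 17)
  coh$strat <- factor(ifelse(seq_len(100) <= 10, "empty", "rest"))
  coh$event[coh$strat == "empty"] <- 0L
  expect_warning(fr <- subgroup_forest(coh, "strat", exposure = "tsr_group"),
                 "undefined")
  expect_true(is.na(fr$hr[fr$subgroup == "empty"]))
})
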