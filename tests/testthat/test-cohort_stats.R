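test_that("Shapiro gate routes skewed data to nonparametric tests", {
  set.seed(7)
  expect_identical(shapiro_gate(rexp(50)), "nonparametric")
  set.seed(7)
  expect_identical(shapiro_gate(rnorm(50)), "parametric")
  expect_error(shapiro_gate(c(1, 2)), "at least 3")
  expect_error(shapiro_gate(rep(2, 10)), "constant")
})

test_that("Wilcoxon rank-sum: exact small-sample p-values and symmetry", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p, 0.10)
  expect_equal(wilcoxon_rank_sum(c(1.5, 2.5), c(1.5, 2.5))$p, 1)
  # symmetry: swapping x and y leaves the two-sided p unchanged
  set.seed(5)
  x <- rnorm(6); y <- rnorm(8) + 1
  expect_equal(wilcoxon_rank_sum(x, y)$p, wilcoxon_rank_sum(y, x)$p)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty")
  # full-enumeration oracle over random tie-free vectors
  for (seed in 1:20) {
    set.seed(seed)
    m <- sample(3:6, 1); n <- sample(3:8, 1)
    x <- runif(m); y <- runif(n) + runif(1, -0.5, 0.5)
    expect_equal(wilcoxon_rank_sum(x, y)$p, oracle_wilcox_p(x, y),
                 tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("Spearman trend: analytic rho and permutation-exact p", {
  down <- spearman_trend(c(9, 7, 5, 3), c(1, 2, 3, 4))
  expect_equal(down$statistic, -1)
  up <- spearman_trend(1:5, 1:5)
  expect_equal(up$statistic, 1)
  expect_error(spearman_trend(rep(2, 4), 1:4), "constant")
  expect_error(spearman_trend(1:4, rep(1, 4)), "constant")
  # time-point labels are coded ordinally
  lab <- spearman_trend(c(4, 3, 2, 1), c("T1", "T1", "T2", "T2"))
  expect_lt(lab$statistic, 0)
  # full-permutation oracle, tie-free and tied covariates, n <= 8
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:7, 1)
    vals <- runif(n)
    tps <- sample(1:3, n, replace = TRUE)
    if (length(unique(tps)) == 1L) tps[1] <- tps[1] %% 3 + 1
    expect_equal(spearman_trend(vals, tps)$p, oracle_spearman_p(vals, tps),
                 tolerance = 1e-12, info = paste("seed", seed))
  }
  # large-n branch agrees with the t-approximation reference
  set.seed(9)
  v <- rnorm(30); tp <- sample(1:3, 30, replace = TRUE)
  ref <- suppressWarnings(stats::cor.test(v, tp, method = "spearman",
                                          exact = FALSE))
  got <- spearman_trend(v, tp)
  expect_equal(got$statistic, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("BH step-up adjustment: worked examples and monotonicity", {
  expect_equal(bh_adjust(c(0.030, 0.020, 0.030)), rep(0.030, 3))
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(numeric(0)), "non-empty")
  for (seed in 1:10) {
    set.seed(seed)
    p <- runif(sample(2:12, 1))
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-15))          # q never below p
    expect_true(all(q <= 1))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))  # order never reversed
  }
})

test_that("response summarization reproduces the trial's response table", {
  tab <- response_summary(c(rep("PR", 4), rep("SD", 7), rep("PD", 4)))
  expect_equal(tab$percent_display[tab$category == "disease_control"], 73)
  expect_equal(tab$percent_display[tab$category == "PR"], 27)
  expect_equal(tab$percent_display[tab$category == "PD"], 27)
  expect_equal(tab$n[tab$category == "disease_control"], 11)
  expect_equal(response_summary(rep("PD", 5))$percent[4], 0)
  expect_equal(response_summary(rep("PR", 3))$percent[4], 100)
  expect_error(response_summary(character(0)), "empty")
  expect_error(response_summary(c("PR", "CR")), "invalid")
})

test_that("Kaplan-Meier product-limit estimation and log-rank test", {
  # two deaths, no censoring: S(1) = 0.5, S(2) = 0
  km <- km_logrank(c(1, 2), c(1, 1), c("A", "A"))
  a <- km$curves$A
  expect_equal(a$surv[a$time == 0], 1)
  expect_equal(a$surv[a$time == 1], 0.5)
  expect_equal(a$surv[a$time == 2], 0)
  expect_false(km$p_defined)                 # single group: no test

  # all censored: curve stays at 1, test undefined
  km2 <- km_logrank(c(5, 6, 7, 8), c(0, 0, 0, 0), c("A", "A", "B", "B"))
  expect_true(all(km2$curves$A$surv == 1))
  expect_true(is.na(km2$p))
  expect_false(km2$p_defined)

  expect_error(km_logrank(c(-1, 2), c(1, 1), c("A", "B")), "negative")
  expect_error(km_logrank(c(1, 2), c(1, 2), c("A", "B")), "0/1")

  # with no censoring the KM curve equals the empirical survivor function
  set.seed(3)
  t <- sample(1:50, 12)
  km3 <- km_logrank(t, rep(1, 12), rep("G", 12))
  g <- km3$curves$G
  emp <- vapply(g$time, function(tt) mean(t > tt), numeric(1))
  expect_equal(g$surv, emp, tolerance = 1e-12)
  # and matches the step-by-step product-limit oracle
  orc <- oracle_km_curve(t, rep(1, 12))
  expect_equal(g$surv, orc$surv, tolerance = 1e-12)

  # log-rank p matches the observed-minus-expected oracle on random data
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20
    times <- round(rexp(n, 0.01)) + 1
    events <- rbinom(n, 1, 0.8)
    groups <- rep(c("A", "B"), each = n / 2)
    if (sum(events) == 0) events[1] <- 1
    got <- km_logrank(times, events, groups)
    expect_equal(got$p, oracle_logrank_p(times, events, groups),
                 tolerance = 1e-8, info = paste("seed", seed))
  }
})

test_that("median survival is read off the curve, Inf when not attained", {
  km <- km_logrank(c(1, 2, 3, 4), c(1, 1, 1, 1), rep("A", 4))
  expect_equal(km_median(km$curves$A), 2)
  km2 <- km_logrank(c(10, 20, 30), c(1, 0, 0), rep("A", 3))
  expect_equal(km_median(km2$curves$A), Inf)
})
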