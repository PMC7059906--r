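test_that("a cohort surviving past tau loses no life years", {
  ch <- lyl_cohort(0, c(96, 97, 98), rep("alive", 3),
                   cause_labels = c("natural", "unnatural"))
  est <- lyl_at_age(ch, 45, tau = 95)
  expect_equal(est$life_exp, 50)
  expect_equal(est$lyl_total, 0)
  expect_equal(unname(est$lyl_by_cause), c(0, 0))
  expect_equal(est$n_at_risk, 3)
})

test_that("conservation holds exactly: LE + cause LYLs partition tau - a", {
  set.seed(13)
  for (i in 1:25) {
    ch <- random_cohort()
    a <- stats::runif(1, 0, 10)
    tau <- a + stats::runif(1, 10, 80)
    est <- tryCatch(lyl_at_age(ch, a, tau), error = function(e) NULL)
    if (is.null(est)) next
    expect_equal(est$life_exp + est$lyl_total, tau - a)
    expect_lt(abs(sum(est$lyl_by_cause) - est$lyl_total), 1e-9)
    expect_gte(est$life_exp, 0)
    expect_lte(est$life_exp, tau - a)
  }
})

test_that("merging all causes into one leaves total LYL unchanged", {
  set.seed(17)
  ch <- random_cohort(n = 60)
  est <- lyl_at_age(ch, 5, tau = 70)
  merged <- lyl_cohort(ch$entry, ch$exit,
                       ifelse(ch$status == "alive", "alive", "dead"),
                       cause_labels = "dead")
  est_m <- lyl_at_age(merged, 5, tau = 70)
  expect_equal(est_m$lyl_total, est$lyl_total)
  expect_equal(unname(est_m$lyl_by_cause), est$lyl_total)
})

test_that("total LYL is non-decreasing in tau", {
  set.seed(19)
  ch <- random_cohort(n = 80)
  taus <- c(40, 55, 70, 85, 95)
  vals <- vapply(taus, function(tau) lyl_at_age(ch, 5, tau)$lyl_total,
                 numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("single-age estimate recovers the constant-hazard closed form", {
  lam <- c(natural = 0.03, unnatural = 0.01)
  ch <- simulate_constant_hazard_cohort(100000, lam, a = 45, tau = 95,
                                        seed = 3)
  est <- lyl_at_age(ch, 45, tau = 95)
  truth <- closed_form_lyl(lam, 45, 95)
  expect_equal(truth$lyl_total, 50 - (1 - exp(-0.04 * 50)) / 0.04)
  expect_lt(abs(est$lyl_total - truth$lyl_total), 0.3)
  expect_lt(abs(est$lyl_by_cause[["natural"]] -
                  truth$lyl_by_cause[["natural"]]), 0.3)
  # the cause split approximates lambda1 : lambda2 = 3 : 1
  expect_lt(abs(est$lyl_by_cause[["natural"]] /
                  est$lyl_by_cause[["unnatural"]] - 3), 0.15)
})

test_that("stacked plot data tops out at 1 and stacks monotonically", {
  ch <- lyl_cohort(0, c(1, 2, 3), c("A", "B", "A"))
  est <- lyl_at_age(ch, 0, tau = 4)
  sd <- lyl_stacked_data(est)
  expect_equal(levels(sd$series), c("survival", "A", "B"))
  at3 <- sd[sd$age == 3, ]
  expect_equal(at3$value[match(c("survival", "A", "B"), at3$series)],
               c(0, 2 / 3, 1))
  top <- sd[sd$series == "B", "value"]
  expect_true(all(abs(top - 1) < 1e-12))
  # each series pointwise >= the previous
  wide <- split(sd$value, sd$series)
  expect_true(all(wide$A >= wide$survival - 1e-15))
  expect_true(all(wide$B >= wide$A - 1e-15))

  # single cause: two series, top identically 1
  ch1 <- lyl_cohort(0, c(1, 3), c("dead", "alive"), cause_labels = "dead")
  sd1 <- lyl_stacked_data(lyl_at_age(ch1, 0, tau = 2))
  expect_equal(nlevels(sd1$series), 2)
  expect_true(all(abs(sd1$value[sd1$series == "dead"] - 1) < 1e-12))
})

test_that("plot method returns a ggplot object", {
  ch <- lyl_cohort(0, c(50, 60, 96), c("natural", "unnatural", "alive"))
  p <- plot(lyl_at_age(ch, 45, tau = 95))
  expect_s3_class(p, "ggplot")
})

test_that("degenerate requests error clearly", {
  ch <- lyl_cohort(0, c(1, 2), c("dead", "dead"))
  expect_error(lyl_at_age(ch, 95, tau = 95), "below tau")
  expect_error(lyl_at_age(ch, 50, tau = 95), "at risk")
})
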