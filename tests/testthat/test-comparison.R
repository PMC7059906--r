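test_that("life-table survival follows the piecewise-exponential closed form", {
  # one year at rate 0.1 from survival 1
  lt <- life_table(0:2, rate = c(0.1, 0.1, 0))
  p <- lifetable_survival(lt, 0, 1)
  expect_equal(pexp_restricted_area(p), (1 - exp(-0.1)) / 0.1)
  expect_equal(pexp_value(p, 1), exp(-0.1))

  # zero mortality: area equals the horizon
  lt0 <- life_table(45:95, rate = rep(0, 51))
  expect_equal(pexp_restricted_area(lifetable_survival(lt0, 45, 95)), 50)

  # constant rate over [a, tau]: geometric sum collapses to the closed form
  lam <- 0.04
  ltc <- life_table(45:95, rate = c(rep(lam, 50), 0))
  expect_equal(pexp_restricted_area(lifetable_survival(ltc, 45, 95)),
               (1 - exp(-lam * 50)) / lam, tolerance = 1e-12)
})

test_that("rates-only and survivor-only tables give identical areas", {
  set.seed(53)
  rates <- stats::runif(30, 0, 0.3)
  surv <- c(1, exp(-cumsum(rates)))
  lt_r <- life_table(40:70, rate = c(rates, 0))
  lt_s <- life_table(40:70, survivor = surv)
  for (a in c(40, 47.5, 55)) {
    expect_lt(abs(pexp_restricted_area(lifetable_survival(lt_r, a, 70)) -
                    pexp_restricted_area(lifetable_survival(lt_s, a, 70))),
              1e-9)
  }
})

test_that("life-table validation enforces consistency and monotonicity", {
  expect_error(life_table(0:2), "at least one")
  expect_error(life_table(c(0, 2, 3), rate = c(0.1, 0.1, 0)), "consecutive")
  expect_error(life_table(0:2, survivor = c(1, 0.5, 0.7)),
               "non-increasing")
  # survivor and rate that disagree
  expect_error(life_table(0:2, survivor = c(1, 0.9, 0.8),
                          rate = c(0.5, 0.5, 0)), "inconsistent")
  # consistent pair passes and uses the survivor column
  s <- c(1, exp(-0.1), exp(-0.25))
  lt <- life_table(0:2, survivor = s, rate = c(0.1, 0.15, 0.2))
  expect_equal(lt$survivor, s)
  # tau beyond the table errors
  expect_error(lifetable_survival(lt, 0, 10), "beyond the last age")
})

test_that("fractional conditioning ages interpolate within the year", {
  lt <- life_table(40:45, rate = c(rep(0.2, 5), 0))
  p <- lifetable_survival(lt, 42.5, 44)
  # memoryless within the constant-rate table
  expect_equal(pexp_restricted_area(p), (1 - exp(-0.2 * 1.5)) / 0.2)
})

test_that("excess LYL is antisymmetric and decomposes by cause", {
  set.seed(59)
  a <- lyl_at_age(random_cohort(n = 150), 5, tau = 70)
  b <- lyl_at_age(random_cohort(n = 150), 5, tau = 70)
  ab <- excess_lyl(a, b)
  ba <- excess_lyl(b, a)
  expect_equal(ab$lyl_diff, -ba$lyl_diff)
  expect_lt(abs(sum(ab$lyl_diff[c("c1", "c2")]) - ab$lyl_diff[["total"]]),
            1e-9)
  # the life-expectancy deficit equals the total LYL difference
  expect_equal(ab$le_diff, ab$lyl_diff[["total"]])
  # identical inputs: all differences zero
  aa <- excess_lyl(a, a)
  expect_true(all(aa$lyl_diff == 0))
})

test_that("difference CIs treat a replicate-free side as fixed", {
  set.seed(61)
  dis <- lyl_at_age(random_cohort(n = 200), 5, tau = 70)
  ref <- lyl_at_age(random_cohort(n = 200), 5, tau = 70)
  bd <- lyl_boot(dis, niter = 40, seed = 7)
  ex <- excess_lyl(bd, ref)
  manual <- stats::quantile(bd$replicates[, "lyl_total"] - ref$lyl_total,
                            c(0.025, 0.975), names = FALSE)
  expect_equal(unname(ex$ci[, "total"]), manual)
  # both sides bootstrapped: paired by iteration, equal niter enforced
  br <- lyl_boot(ref, niter = 40, seed = 8)
  ex2 <- excess_lyl(bd, br)
  manual2 <- stats::quantile(bd$replicates[, "lyl_total"] -
                               br$replicates[, "lyl_total"],
                             c(0.025, 0.975), names = FALSE)
  expect_equal(unname(ex2$ci[, "total"]), manual2)
  br2 <- lyl_boot(ref, niter = 30, seed = 8)
  expect_error(excess_lyl(bd, br2), "unequal niter")
})

test_that("excess versus a zero-mortality life table returns the cohort's own LYL", {
  set.seed(67)
  ch <- random_cohort(n = 150)
  est <- lyl_at_age(ch, 5, tau = 70)
  lt0 <- life_table(0:70, rate = rep(0, 71))
  ex <- excess_lyl_vs_lifetable(est, lt0)
  expect_equal(ex$excess, est$lyl_total)
  expect_equal(ex$reference_lyl, 0)
})

test_that("life-table comparison handles range results with onset weights", {
  set.seed(71)
  ch <- random_cohort(n = 400)
  tab <- lyl_over_range(ch, 0, 20, tau = 70)
  w <- weights_from_onsets(stats::runif(60, 0, 21), 0, 20)
  lt <- life_table(0:70, rate = c(rep(0.01, 70), 0))
  ex <- excess_lyl_vs_lifetable(tab, lt, weights = w)
  ws <- weighted_summary(tab, w)
  ref <- sum((w / sum(w)) * vapply(as.integer(names(w)), function(a) {
    lifetable_lyl(lt, a, 70)
  }, numeric(1)))
  expect_equal(ex$excess, ws$lyl_total - ref)
  # bootstrapped input gains a CI around the same point estimate
  bt <- lyl_boot(tab, niter = 25, seed = 12)
  exb <- excess_lyl_vs_lifetable(bt, lt, weights = w)
  expect_equal(exb$excess, ex$excess)
  expect_true(exb$ci[["lower"]] <= exb$ci[["upper"]])
})

test_that("mismatched tau or conditioning age is rejected", {
  ch <- lyl_cohort(0, c(50, 60), c("dead", "dead"))
  a <- lyl_at_age(ch, 0, 95)
  b <- lyl_at_age(ch, 0, 90)
  expect_error(excess_lyl(a, b), "tau")
  d <- lyl_at_age(ch, 10, 95)
  expect_error(excess_lyl(a, d), "conditioning ages")
})
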