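test_that("identical records give zero-width intervals", {
  ch <- lyl_cohort(0, rep(50, 40), rep("dead", 40))
  est <- lyl_at_age(ch, 0, tau = 95)
  bt <- lyl_boot(est, niter = 25, seed = 4)
  expect_equal(unname(bt$ci["lower", ]), unname(bt$ci["upper", ]))
  expect_equal(bt$ci[["lower", "lyl_total"]], est$lyl_total)
})

test_that("the same seed reproduces replicates bit for bit", {
  set.seed(31)
  ch <- random_cohort(n = 150)
  est <- lyl_at_age(ch, 2, tau = 80)
  b1 <- lyl_boot(est, niter = 30, seed = 42)
  b2 <- lyl_boot(est, niter = 30, seed = 42)
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(b1$ci, b2$ci)
  b3 <- lyl_boot(est, niter = 30, seed = 43)
  expect_false(identical(b1$replicates, b3$replicates))
  # extending the run preserves the earlier replicates
  b4 <- lyl_boot(est, niter = 45, seed = 42)
  expect_identical(b4$replicates[1:30, ], b1$replicates)
})

test_that("every replicate satisfies the conservation identity", {
  set.seed(37)
  ch <- random_cohort(n = 120)
  est <- lyl_at_age(ch, 3, tau = 75)
  bt <- lyl_boot(est, niter = 40, seed = 9)
  horizon <- est$tau - est$condition_age
  expect_true(all(abs(bt$replicates[, "life_exp"] +
                        bt$replicates[, "lyl_total"] - horizon) < 1e-9))
  cause_cols <- paste0("lyl_", attr(ch, "cause_labels"))
  expect_true(all(abs(rowSums(bt$replicates[, cause_cols, drop = FALSE]) -
                        bt$replicates[, "lyl_total"]) < 1e-9))
})

test_that("CI width shrinks with cohort size", {
  lam <- c(dead = 0.04)
  widths <- vapply(c(400, 6400), function(n) {
    ch <- simulate_constant_hazard_cohort(n, lam, a = 45, tau = 95,
                                          seed = 21)
    bt <- lyl_boot(lyl_at_age(ch, 45, 95), niter = 60, seed = 2)
    bt$ci["upper", "lyl_total"] - bt$ci["lower", "lyl_total"]
  }, numeric(1))
  # 16x the data should shrink the width by roughly 4; allow slack
  expect_lt(widths[2], widths[1] / 2)
})

test_that("bootstrapping a range table propagates through weighting", {
  set.seed(43)
  ch <- random_cohort(n = 300)
  tab <- lyl_over_range(ch, 0, 20, tau = 80)
  bt <- lyl_boot(tab, niter = 30, seed = 8)
  expect_equal(dim(bt$replicates), c(30, 21, 4))
  w <- weights_from_onsets(stats::runif(40, 0, 21), 0, 20)
  ws <- weighted_summary(bt, w)
  expect_equal(ws$kind, "summary")
  # the point estimate of the weighted bootstrap matches the plain summary
  plain <- weighted_summary(tab, w)
  expect_equal(unname(ws$point_quantities["lyl_total"]), plain$lyl_total)
  expect_true(all(ws$ci["lower", ] <= ws$ci["upper", ]))
  # per-replicate weighted conservation
  expect_true(all(abs(ws$replicates[, "life_exp"] +
                        ws$replicates[, "lyl_total"] - plain$horizon)
                  < 1e-9))
})

test_that("running CI endpoints converge and end at the reported interval", {
  set.seed(47)
  ch <- random_cohort(n = 200)
  est <- lyl_at_age(ch, 2, tau = 80)
  bt <- lyl_boot(est, niter = 120, seed = 3)
  st <- ci_stability(bt)
  expect_equal(st$lower[nrow(st)], bt$ci[["lower", "lyl_total"]])
  expect_equal(st$upper[nrow(st)], bt$ci[["upper", "lyl_total"]])
  # identical-record cohort: flat series, converged immediately
  flat <- lyl_boot(lyl_at_age(lyl_cohort(0, rep(50, 30), rep("dead", 30)),
                              0, 95), niter = 40, seed = 5)
  stf <- ci_stability(flat)
  expect_true(attr(stf, "converged"))
  expect_true(all(stf$lower == stf$lower[1]))
})

test_that("bootstrap argument validation", {
  ch <- lyl_cohort(0, c(50, 60), c("dead", "dead"))
  est <- lyl_at_age(ch, 0, 95)
  expect_error(lyl_boot(est, niter = 1), "at least 2")
  expect_error(lyl_boot(est, niter = 10, level = 1.2), "level")
})
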