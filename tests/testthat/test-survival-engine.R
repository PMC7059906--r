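test_that("product-limit estimator matches hand calculations", {
  ch <- lyl_cohort(0, c(1, 2, 3), c("dead", "dead", "dead"))
  s <- fit_conditional_survival(ch, 0)
  expect_equal(s$jump_ages, c(1, 2, 3))
  expect_equal(s$values, c(2 / 3, 1 / 3, 0))

  # all censored: a valid curve with no jumps, identically 1
  ch2 <- lyl_cohort(0, c(5, 9), c("alive", "alive"), cause_labels = "dead")
  s2 <- fit_conditional_survival(ch2, 0)
  expect_length(s2$jump_ages, 0)
  expect_equal(stepcurve_value(s2, c(0, 4, 100)), c(1, 1, 1))

  # empty risk set with no later entrants errors
  expect_error(fit_conditional_survival(ch, 10), "at risk")
})

test_that("Aalen-Johansen CIFs match hand calculations and stack to 1", {
  ch <- lyl_cohort(0, c(1, 2, 3), c("A", "B", "A"))
  fit <- fit_competing_risks(ch, 0)
  expect_equal(fit$cifs$A$values, c(1 / 3, 1 / 3, 2 / 3))
  expect_equal(fit$cifs$B$values, c(0, 1 / 3, 1 / 3))
  expect_equal(fit$survival$values, c(2 / 3, 1 / 3, 0))

  # single cause: CIF is the complement of survival at every jump
  ch1 <- lyl_cohort(0, c(2, 4, 7, 9), c("dead", "dead", "alive", "dead"))
  f1 <- fit_competing_risks(ch1, 0)
  expect_equal(f1$cifs$dead$values, 1 - f1$survival$values)
})

test_that("restricted_area integrates step curves exactly", {
  crv <- new_curve <- fit_conditional_survival(
    lyl_cohort(0, c(1, 2, 3), c("dead", "dead", "dead")), 0)
  expect_equal(restricted_area(crv, 0, 3), 1 + 2 / 3 + 1 / 3)
  # flat survivor curve: area is the interval width
  flat <- fit_conditional_survival(
    lyl_cohort(0, c(2, 5), c("alive", "alive"), cause_labels = "dead"), 0)
  expect_equal(restricted_area(flat, 0, 5), 5)
  expect_equal(restricted_area(flat, 1.5, 4.25), 2.75)
  expect_error(restricted_area(flat, 3, 3), "exceed")

  # two-step curve: 1 on [0,2), 0.5 on [2,5); area on [0,5] is 3.5
  ch <- lyl_cohort(0, c(2, 6), c("dead", "alive"), cause_labels = "dead")
  s <- fit_conditional_survival(ch, 0)
  expect_equal(s$values, 0.5)
  expect_equal(restricted_area(s, 0, 5), 1 * 2 + 0.5 * 3)

  # a censoring tied with a death stays in the risk set for that event
  tied <- lyl_cohort(0, c(2, 2), c("dead", "alive"), cause_labels = "dead")
  expect_equal(fit_conditional_survival(tied, 0)$values, 0.5)
})

test_that("restricted_area agrees with a brute-force grid oracle", {
  set.seed(41)
  for (i in 1:20) {
    ch <- random_cohort()
    a <- stats::runif(1, 0, 5)
    fit <- tryCatch(fit_competing_risks(ch, a), error = function(e) NULL)
    if (is.null(fit)) next
    tau <- a + stats::runif(1, 5, 60)
    s <- fit$survival
    expect_equal(restricted_area(s, a, tau),
                 oracle_step_area(s$jump_ages, s$values, 1, a, tau))
    f <- fit$cifs[[1]]
    expect_equal(restricted_area(f, a, tau),
                 oracle_step_area(f$jump_ages, f$values, 0, a, tau))
  }
})

test_that("survivor curves are monotone and CIFs stack to 1 at every jump", {
  set.seed(7)
  for (i in 1:40) {
    ch <- random_cohort()
    a <- sample(c(0, 10, 30), 1)
    fit <- tryCatch(fit_competing_risks(ch, a), error = function(e) NULL)
    if (is.null(fit)) next
    s <- fit$survival$values
    expect_true(all(diff(s) <= 1e-15))
    expect_true(all(s >= -1e-15 & s <= 1 + 1e-15))
    tot <- s
    for (f in fit$cifs) {
      expect_true(all(diff(f$values) >= -1e-15))
      tot <- tot + f$values
    }
    expect_true(all(abs(tot - 1) <= 1e-12))
  }
})

test_that("delayed entrants join the risk set late without touching the curve below their entry", {
  base <- lyl_cohort(0, c(10, 20, 30, 40), c("A", "B", "A", "alive"),
                     cause_labels = c("A", "B"))
  f0 <- fit_competing_risks(base, 0)
  added <- lyl_cohort(c(0, 0, 0, 0, 25), c(10, 20, 30, 40, 50),
                      c("A", "B", "A", "alive", "A"),
                      cause_labels = c("A", "B"))
  f1 <- fit_competing_risks(added, 0)
  below <- f1$survival$jump_ages < 25
  expect_equal(f1$survival$values[below],
               f0$survival$values[f0$survival$jump_ages < 25])
  # the late entrant (entry 25) is at risk at age 30: risk set there is
  # {exit 30, exit 40, entrant}, so the hazard factor is 1 - 1/3, whereas
  # without the entrant it was 1 - 1/2
  s20 <- stepcurve_value(f1$survival, 20)
  s30 <- stepcurve_value(f1$survival, 30)
  expect_equal(s30 / s20, 1 - 1 / 3)
  expect_equal(stepcurve_value(f0$survival, 30) /
                 stepcurve_value(f0$survival, 20), 1 - 1 / 2)
})

test_that("left-truncated fits agree with survival::survfit on tie-free data", {
  skip_if_not_installed("survival")
  set.seed(99)
  n <- 500
  entry <- ifelse(stats::runif(n) < 0.4, stats::runif(n, 0, 30), 0)
  exit <- entry + stats::rexp(n, 0.04) + 0.01
  status <- sample(c("alive", "c1", "c2"), n, TRUE, prob = c(0.3, 0.5, 0.2))
  ch <- lyl_cohort(entry, pmin(exit, 90), status,
                   cause_labels = c("c1", "c2"))
  for (a in c(0, 20)) {
    keep <- ch$exit > a
    f <- fit_competing_risks(ch, a)
    sf <- survival::survfit(
      survival::Surv(pmax(entry, a)[keep], ch$exit[keep],
                     ch$status[keep] != "alive") ~ 1)
    i <- match(f$survival$jump_ages, sf$time)
    expect_equal(f$survival$values, sf$surv[i], tolerance = 1e-12)
    st <- factor(ifelse(ch$status == "alive", "cens", ch$status),
                 levels = c("cens", "c1", "c2"))
    sf2 <- survival::survfit(
      survival::Surv(pmax(entry, a)[keep], ch$exit[keep], st[keep]) ~ 1)
    for (k in c("c1", "c2")) {
      j <- match(f$cifs[[k]]$jump_ages, sf2$time)
      expect_equal(f$cifs[[k]]$values, unname(sf2$pstate[j, k]),
                   tolerance = 1e-12)
    }
  }
})

test_that("estimator converges to the constant-hazard closed form", {
  lam <- c(c1 = 0.03, c2 = 0.02)
  ch <- simulate_constant_hazard_cohort(50000, lam, a = 45, tau = 95,
                                        seed = 11)
  s <- fit_conditional_survival(ch, 45)
  grid <- seq(45.5, 94.5, by = 1)
  expect_lt(max(abs(stepcurve_value(s, grid) -
                      exp(-sum(lam) * (grid - 45)))), 0.01)
  fit <- fit_competing_risks(ch, 45)
  truth <- lam["c1"] / sum(lam) * (1 - exp(-sum(lam) * (grid - 45)))
  expect_lt(max(abs(stepcurve_value(fit$cifs$c1, grid) - truth)), 0.01)
})

test_that("numbers_at_risk counts open intervals correctly", {
  ch <- lyl_cohort(c(0, 0, 50), c(40, 60, 70),
                   c("dead", "alive", "dead"))
  tab <- numbers_at_risk(ch, c(45, 55, -1))
  expect_equal(tab$n_at_risk, c(1, 2, 0))
  expect_equal(tab$n_events_so_far, c(1, 1, 0))
  expect_error(numbers_at_risk(ch, numeric(0)), "non-empty")
})

test_that("cohort construction enforces its invariants", {
  expect_error(lyl_cohort(5, 5, "dead"), "exceed")
  expect_error(lyl_cohort(0, 10, "mystery", cause_labels = "dead"),
               "unknown status")
  expect_error(lyl_cohort(0, 10, "dead", cause_labels = c("dead", "dead")),
               "unique")
  # numeric 0/1 status maps to censored / single cause
  ch <- lyl_cohort(0, c(1, 2), c(0, 1))
  expect_equal(ch$status, c("alive", "dead"))
  expect_equal(attr(ch, "cause_labels"), "dead")
})
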