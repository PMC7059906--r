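# Independent oracles used across the suite.

# Hand recursion for the product-limit / Aalen-Johansen estimators on small
# cohorts with everyone entering at 0 and distinct exit times: walk the exits
# in time order, removing one person at a time; at a death, the cause's CIF
# gains S/at_risk and S shrinks by the factor (1 - 1/at_risk).
oracle_km_aj <- function(exit, status, causes, censor = "alive") {
  ord <- order(exit)
  s <- 1
  f <- stats::setNames(numeric(length(causes)), causes)
  at_risk <- length(exit)
  times <- numeric(0)
  surv <- numeric(0)
  cifs <- NULL
  for (i in ord) {
    if (status[i] != censor) {
      f[status[i]] <- f[status[i]] + s / at_risk
      s <- s * (1 - 1 / at_risk)
      times <- c(times, exit[i])
      surv <- c(surv, s)
      cifs <- rbind(cifs, f)
    }
    at_risk <- at_risk - 1
  }
  list(times = times, surv = surv,
       cif = if (is.null(cifs)) matrix(0, 0, length(causes)) else
         unname(cifs))
}

# Restricted area of a right-continuous step function given by jump times
# and post-jump values, by brute-force segment summation on a value grid.
oracle_step_area <- function(times, values, v0, from, to) {
  grid <- sort(unique(c(from, times[times > from & times < to], to)))
  vals <- vapply(grid[-length(grid)], function(t) {
    ix <- which(times <= t)
    if (!length(ix)) v0 else values[max(ix)]
  }, numeric(1))
  sum(vals * diff(grid))
}

# Random small cohort for property tests.
random_cohort <- function(n = NULL, causes = c("c1", "c2")) {
  if (is.null(n)) n <- sample(2:30, 1)
  entry <- ifelse(stats::runif(n) < 0.3, stats::runif(n, 0, 40), 0)
  exit <- entry + stats::rexp(n, 0.05) + 0.01
  status <- sample(c("alive", causes), n, replace = TRUE)
  lyl_cohort(entry, exit, status, cause_labels = causes)
}
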