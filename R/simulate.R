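#' Simulation scenario for a population with disease onset
#'
#' Defines the generating mechanism for synthetic populations: everyone is
#' followed from `start_age`, may acquire a disease (onset hazard), dies of
#' one of the competing causes (pre-onset hazards before onset, post-onset
#' hazards after), and is administratively censored at `tau_censor`.
#'
#' Hazards are piecewise constant on one-year age intervals: each hazard is
#' either a single non-negative rate (constant at all ages) or a numeric
#' vector giving the rate on `[0,1), [1,2), ...` with the last value
#' extended to older ages. Competing causes are realized through independent
#' piecewise-exponential latent failure times per cause, the earliest cause
#' winning, which is equivalent to simulating from the cause-specific
#' hazards.
#'
#' The default scenario emulates a registry-style population of 100,000
#' followed from birth and censored at age 95, with two mutually exclusive
#' causes of death ("natural", with a Gompertz-like rate doubling roughly
#' every 8 years, and "unnatural", roughly age-constant), a disease of
#' interest affecting about a third of the population with onset ages
#' spanning 1-95 years, and post-onset mortality elevated for both causes.
#'
#' @param n population size.
#' @param tau_censor administrative censoring age (years).
#' @param start_age entry age for everyone (default 0, followed from birth).
#' @param onset_rate onset hazard (scalar or per-year vector).
#' @param onset_min_age no onsets before this age (default 1).
#' @param pre_onset named list of cause hazards before onset (and for the
#'   never-diseased).
#' @param post_onset named list of cause hazards after onset; same cause
#'   names as `pre_onset`.
#' @param censor_label status string for censored records.
#' @return Object of class `lyl_scenario`.
#' @export
simulation_scenario <- function(n = 100000,
                                tau_censor = 95,
                                start_age = 0,
                                onset_rate = 0.0053,
                                onset_min_age = 1,
                                pre_onset = list(
                                  natural = 4.4e-05 * exp(0.092 * (0:94 + 0.5)),
                                  unnatural = 5.8e-04),
                                post_onset = list(
                                  natural = 1.1e-04 * exp(0.092 * (0:94 + 0.5)),
                                  unnatural = 2.3e-03),
                                censor_label = "alive") {
  if (n < 1) stop("n must be at least 1")
  if (tau_censor <= start_age) stop("tau_censor must exceed start_age")
  causes <- names(pre_onset)
  if (is.null(causes) || any(!nzchar(causes))) {
    stop("pre_onset hazards must be a named list of causes")
  }
  if (!identical(sort(causes), sort(names(post_onset)))) {
    stop("pre_onset and post_onset must name the same causes")
  }
  chk <- function(h, nm) {
    if (!is.numeric(h) || anyNA(h) || any(h < 0)) {
      stop("hazard '", nm, "' must be non-negative numeric")
    }
  }
  for (k in causes) {
    chk(pre_onset[[k]], k)
    chk(post_onset[[k]], k)
  }
  chk(onset_rate, "onset_rate")
  structure(list(n = as.integer(n), tau_censor = tau_censor,
                 start_age = start_age, onset_rate = onset_rate,
                 onset_min_age = onset_min_age, pre_onset = pre_onset,
                 post_onset = post_onset[causes],
                 cause_labels = causes, censor_label = censor_label),
            class = "lyl_scenario")
}

# Expand a scalar-or-vector hazard to a per-year rate vector long enough to
# cover [0, horizon); the last value extends beyond.
expand_rates <- function(h, horizon) {
  L <- ceiling(horizon) + 1L
  if (length(h) == 1L) return(rep(h, L))
  if (length(h) < L) h <- c(h, rep(h[length(h)], L - length(h)))
  h[seq_len(L)]
}

# Draw piecewise-exponential event times: cumulative hazard is piecewise
# linear on the unit age grid; invert H(t) = H(t0) + E with E ~ Exp(1).
# Returns Inf when the total hazard is exhausted (only possible with
# trailing zero rates, which cannot happen after expand_rates unless the
# hazard is 0 there).
rpwexp_from <- function(t0, rates) {
  breaks <- seq(0, length(rates))
  cum <- c(0, cumsum(rates))
  e <- stats::rexp(length(t0))
  i0 <- pmin(findInterval(t0, breaks), length(rates))
  h0 <- cum[i0] + (t0 - breaks[i0]) * rates[i0]
  v <- h0 + e
  j <- findInterval(v, cum, rightmost.closed = FALSE)
  j <- pmin(j, length(rates))
  t <- breaks[j] + (v - cum[j]) / rates[j]
  # beyond the grid the last rate extends; rate 0 anywhere gives Inf there
  t[!is.finite(t)] <- Inf
  t
}

#' Simulate a population with disease onset and competing causes of death
#'
#' Draws, for each person, a latent onset age and latent cause-specific
#' death ages (pre-onset hazards until onset, post-onset hazards after);
#' the earliest cause wins and everyone still alive at the scenario's
#' `tau_censor` is censored there. Reproducible: identical scenario and
#' seed give an identical population.
#'
#' @param scenario a [simulation_scenario()].
#' @param seed integer RNG seed.
#' @return An [lyl_cohort()] with `entry = start_age`, the realized exit
#'   age, status (cause or censor label) and `onset` (NA for the
#'   never-diseased or onsets unobserved before death/censoring).
#' @examples
#' pop <- simulate_population(simulation_scenario(n = 500), seed = 1)
#' table(pop$status)
#' @export
simulate_population <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "lyl_scenario"))
  set.seed(as.integer(seed))
  n <- scenario$n
  horizon <- scenario$tau_censor
  causes <- scenario$cause_labels
  K <- length(causes)
  on_rates <- expand_rates(scenario$onset_rate, horizon)
  if (scenario$onset_min_age > 0) {
    on_rates[seq_len(min(length(on_rates),
                         ceiling(scenario$onset_min_age)))] <- 0
  }
  t0 <- rep(scenario$start_age, n)
  onset <- rpwexp_from(t0, on_rates)
  pre <- vapply(causes, function(k) {
    rpwexp_from(t0, expand_rates(scenario$pre_onset[[k]], horizon))
  }, numeric(n))
  pre <- matrix(pre, nrow = n, dimnames = list(NULL, causes))
  death_pre <- do.call(pmin, as.data.frame(pre))
  cause_pre <- max.col(-pre, ties.method = "first")
  diseased <- onset < pmin(death_pre, horizon)
  death <- death_pre
  cause <- cause_pre
  if (any(diseased)) {
    post <- vapply(causes, function(k) {
      rates <- expand_rates(scenario$post_onset[[k]], horizon)
      out <- rep(Inf, n)
      out[diseased] <- rpwexp_from(onset[diseased], rates)
      out
    }, numeric(n))
    post <- matrix(post, nrow = n, dimnames = list(NULL, causes))
    death_post <- do.call(pmin, as.data.frame(post))
    cause_post <- max.col(-post, ties.method = "first")
    death[diseased] <- death_post[diseased]
    cause[diseased] <- cause_post[diseased]
  }
  censored <- death >= horizon
  exit <- pmin(death, horizon)
  status <- ifelse(censored, scenario$censor_label, causes[cause])
  lyl_cohort(entry = scenario$start_age, exit = exit, status = status,
             censor_label = scenario$censor_label, cause_labels = causes,
             onset = ifelse(diseased, onset, NA_real_))
}

#' Closed-form Life Years Lost under constant cause-specific hazards
#'
#' Analytic oracle: with constant cause-specific hazards summing to Lambda,
#' the tau-restricted life expectancy at age a is
#' `(1 - exp(-Lambda (tau - a))) / Lambda` (or `tau - a` when Lambda = 0),
#' and each cause's LYL is its proportional share `lambda_k / Lambda` of
#' the total life lost.
#'
#' @param lambda_by_cause named non-negative rates per cause.
#' @param a conditioning age; @param tau restriction age.
#' @return A list shaped like an `lyl_estimate`: `condition_age`, `tau`,
#'   `life_exp`, `lyl_total`, `lyl_by_cause`.
#' @export
closed_form_lyl <- function(lambda_by_cause, a, tau) {
  if (a >= tau) stop("a must be below tau")
  lam <- unlist(lambda_by_cause)
  if (any(lam < 0)) stop("rates must be non-negative")
  big <- sum(lam)
  delta <- tau - a
  le <- if (big == 0) delta else (1 - exp(-big * delta)) / big
  lyl <- delta - le
  by_cause <- if (big == 0) lam * 0 else lam / big * lyl
  list(condition_age = a, tau = tau, life_exp = le, lyl_total = lyl,
       lyl_by_cause = by_cause)
}

#' Constant-hazard landmark cohort with known truth
#'
#' Convenience generator for validation: everyone enters at age `a`, dies
#' of one of the competing constant-hazard causes or is censored at `tau`.
#' The estimand of [lyl_at_age()] at `a` is then [closed_form_lyl()]
#' exactly.
#'
#' @param n cohort size.
#' @param lambda_by_cause named constant rates per cause.
#' @param a entry/conditioning age; @param tau censoring/restriction age.
#' @param seed integer RNG seed.
#' @return An [lyl_cohort()].
#' @export
simulate_constant_hazard_cohort <- function(n, lambda_by_cause, a, tau,
                                            seed = 1) {
  sc <- simulation_scenario(
    n = n, tau_censor = tau, start_age = a, onset_rate = 0,
    onset_min_age = 0,
    pre_onset = as.list(lambda_by_cause),
    post_onset = as.list(lambda_by_cause))
  simulate_population(sc, seed = seed)
}
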