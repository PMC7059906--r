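# ---------------------------------------------------------------------------
# Landmark-conditioned nonparametric estimation with delayed entry.
#
# Conventions (fixed throughout the package):
#  * curves are right-continuous step functions; the value at a jump age is
#    the post-jump value, and integration uses the value on [t_j, t_{j+1});
#  * the risk set at an event age t counts individuals with entry <= t <=
#    exit: individuals censored exactly at t remain at risk for the tied
#    event, and delayed entrants join at their entry age;
#  * individuals whose entry age exceeds the conditioning age enter the risk
#    set late (standard left-truncated product-limit behaviour).
# ---------------------------------------------------------------------------

#' Step-function curve
#'
#' Internal constructor for right-continuous step curves (survivor functions
#' start at 1 and are non-increasing; cumulative incidence functions start at
#' 0 and are non-decreasing).
#'
#' @keywords internal
#' @noRd
new_stepcurve <- function(start_age, jump_ages, values,
                          type = c("survival", "cif")) {
  type <- match.arg(type)
  structure(list(start_age = start_age, jump_ages = as.numeric(jump_ages),
                 values = as.numeric(values), type = type),
            class = "lyl_stepcurve")
}

#' Evaluate a step curve
#'
#' Right-continuous evaluation: at a jump age the post-jump value is
#' returned; before the first jump the curve equals 1 (survivor) or
#' 0 (cumulative incidence).
#'
#' @param curve an `lyl_stepcurve`.
#' @param t numeric vector of ages.
#' @return numeric vector of curve values.
#' @export
stepcurve_value <- function(curve, t) {
  v0 <- if (curve$type == "survival") 1 else 0
  i <- findInterval(t, curve$jump_ages)
  out <- rep(v0, length(t))
  out[i > 0L] <- curve$values[i[i > 0L]]
  out[t < curve$start_age] <- NA_real_
  out
}

#' @export
print.lyl_stepcurve <- function(x, ...) {
  cat(sprintf("%s step curve from age %g with %d jump(s)\n",
              if (x$type == "survival") "Survivor" else "Cumulative incidence",
              x$start_age, length(x$jump_ages)))
  invisible(x)
}

# Pre-sorted representation shared by all landmark fits on one cohort:
# entry ages sorted, exit ages sorted with aligned cause codes. Risk sets at
# any event age t > a reduce to two findInterval() counts because everyone
# with exit <= a contributes equally to both.
aj_prepare <- function(cohort) {
  cause <- cohort_cause_index(cohort)
  ox <- order(cohort$exit)
  list(entry_sorted = sort(cohort$entry),
       exit_sorted = cohort$exit[ox],
       cause_sorted = cause[ox],
       n = nrow(cohort),
       causes = cohort_causes(cohort))
}

# Core product-limit / Aalen-Johansen fit conditional on being under
# observation at `condition_age`. Returns event times (> condition_age),
# survivor values and a matrix of per-cause CIF values (one column per cause).
aj_fit <- function(prep, condition_age) {
  xs <- prep$exit_sorted
  first <- findInterval(condition_age, xs) + 1L  # first exit > condition_age
  if (first > prep$n) {
    stop("no individuals at risk at or after age ", condition_age)
  }
  K <- length(prep$causes)
  ev <- which(prep$cause_sorted > 0L & xs > condition_age)
  if (!length(ev)) {
    return(list(times = numeric(0), surv = numeric(0),
                cif = matrix(0, 0, K, dimnames = list(NULL, prep$causes))))
  }
  times <- unique(xs[ev])          # already sorted
  L <- length(times)
  # risk set at t: #(entry <= t) - #(exit < t); ties at t stay in.
  n_enter <- findInterval(times, prep$entry_sorted)
  n_gone <- findInterval(times, xs, left.open = TRUE)
  atrisk <- n_enter - n_gone
  idx <- match(xs[ev], times)
  d <- matrix(tabulate((prep$cause_sorted[ev] - 1L) * L + idx, nbins = L * K),
              L, K, dimnames = list(NULL, prep$causes))
  dtot <- rowSums(d)
  surv <- cumprod(1 - dtot / atrisk)
  sprev <- c(1, surv[-L])
  cif <- apply(d / atrisk, 2L, function(h) cumsum(sprev * h))
  cif <- matrix(cif, L, K, dimnames = list(NULL, prep$causes))
  list(times = times, surv = surv, cif = cif)
}

#' Conditional survival by the product-limit estimator
#'
#' Fits the Kaplan-Meier (product-limit) estimator of survival conditional on
#' being alive and under observation at `condition_age`, handling delayed
#' entry (left truncation) and right censoring. This is the landmark
#' construction: mortality information comes only from ages beyond the
#' conditioning age, from individuals at risk there (individuals entering
#' follow-up after the conditioning age join the risk set at their entry
#' age).
#'
#' @param cohort an [lyl_cohort()].
#' @param condition_age landmark age (years); the curve starts there at 1.
#' @return An `lyl_stepcurve` of type `"survival"`.
#' @examples
#' ch <- lyl_cohort(0, c(1, 2, 3), c("dead", "dead", "dead"))
#' fit_conditional_survival(ch, 0)
#' @export
fit_conditional_survival <- function(cohort, condition_age) {
  fit <- aj_fit(aj_prepare(cohort), condition_age)
  new_stepcurve(condition_age, fit$times, fit$surv, "survival")
}

#' Cause-specific cumulative incidence by the Aalen-Johansen estimator
#'
#' Fits the survivor curve together with one cumulative incidence function
#' (CIF) per death cause, conditional on being at risk at `condition_age`.
#' The CIF increment at an event age t is S(t-) d_k / n, so the survivor
#' curve and the stacked CIFs always partition the unit probability:
#' S(t) + sum_k F_k(t) = 1 at every jump.
#'
#' @inheritParams fit_conditional_survival
#' @return An object of class `lyl_crcurves`: a list with elements
#'   `survival` (an `lyl_stepcurve`), `cifs` (named list of `lyl_stepcurve`,
#'   one per cause) and `condition_age`.
#' @export
fit_competing_risks <- function(cohort, condition_age) {
  causes <- cohort_causes(cohort)
  if (!length(causes)) stop("cohort has no cause labels")
  fit <- aj_fit(aj_prepare(cohort), condition_age)
  cifs <- lapply(causes, function(k) {
    new_stepcurve(condition_age, fit$times, fit$cif[, k], "cif")
  })
  names(cifs) <- causes
  structure(list(survival = new_stepcurve(condition_age, fit$times, fit$surv,
                                          "survival"),
                 cifs = cifs, condition_age = condition_age),
            class = "lyl_crcurves")
}

#' Area under a step curve over an age interval
#'
#' Exact integral of a right-continuous step function on
#' `[from_age, to_age]`: each inter-jump segment contributes its value times
#' its width. For a survivor curve this is the restricted mean lifetime
#' (years lived) over the interval; for a CIF it is the cause's share of
#' life lost.
#'
#' @param curve an `lyl_stepcurve`.
#' @param from_age,to_age interval bounds (years), `from_age >=`
#'   the curve's start age and `to_age > from_age`.
#' @return Area in years.
#' @export
restricted_area <- function(curve, from_age, to_age) {
  if (to_age <= from_age) stop("to_age must exceed from_age")
  if (from_age < curve$start_age) {
    stop("from_age is below the curve's start age")
  }
  j <- curve$jump_ages
  inner <- j[j > from_age & j < to_age]
  grid <- c(from_age, inner, to_age)
  vals <- stepcurve_value(curve, grid[-length(grid)])
  sum(vals * diff(grid))
}

#' Numbers at risk and cumulative events at given ages
#'
#' Diagnostic for risk-set sufficiency: nonparametric estimates become
#' unreliable where few individuals remain under observation (typically at
#' old ages), so inspect the risk set before trusting per-age estimates.
#'
#' @param cohort an [lyl_cohort()].
#' @param ages numeric vector of ages to evaluate.
#' @return A data.frame with columns `age`, `n_at_risk` (records with
#'   `entry <= age < exit`) and `n_events_so_far` (deaths at or before
#'   `age`).
#' @export
numbers_at_risk <- function(cohort, ages) {
  if (!length(ages)) stop("ages must be non-empty")
  cl <- cohort_censor(cohort)
  dead <- cohort$status != cl
  data.frame(
    age = ages,
    n_at_risk = vapply(ages, function(a) {
      sum(cohort$entry <= a & a < cohort$exit)
    }, numeric(1)),
    n_events_so_far = vapply(ages, function(a) {
      sum(dead & cohort$exit <= a)
    }, numeric(1))
  )
}
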