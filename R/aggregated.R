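#' Aggregated diseased-population table
#'
#' For settings where individual-level data are unavailable even for the
#' diseased group, the method needs only (i) the number of new cases at each
#' age and (ii) age-specific mortality rates among those with the disease
#' (or age-specific survivor proportions). The mortality column is
#' interpreted as the conditional-on-onset mortality experienced from each
#' age onward, so the landmark construction is implicit in the table.
#'
#' @param age integer vector of consecutive ages.
#' @param rate,survivor mortality rates per person-year on `[x, x+1)` or
#'   survivor proportions at each exact age; at least one is required.
#' @param new_cases number of new disease cases at each age (>= 0, positive
#'   total).
#' @return Object of class `lyl_aggregated_cohort` wrapping a
#'   [life_table()] plus the new-case counts.
#' @export
aggregated_cohort <- function(age, rate = NULL, survivor = NULL, new_cases) {
  if (length(new_cases) != length(age)) {
    stop("new_cases must match age in length")
  }
  if (anyNA(new_cases) || any(new_cases < 0)) {
    stop("new_cases must be non-negative")
  }
  if (sum(new_cases) <= 0) stop("new_cases must have a positive total")
  lt <- life_table(age, survivor = survivor, rate = rate)
  structure(list(lifetable = lt, new_cases = as.numeric(new_cases),
                 age = lt$age),
            class = "lyl_aggregated_cohort")
}

#' Excess Life Years Lost at one age from aggregated data
#'
#' Both the diseased group and the reference population enter as age-indexed
#' tables; each is converted to a conditional piecewise-exponential survival
#' curve from `age_specific` to `tau`, and LYL is `(tau - age_specific)`
#' minus the restricted area. Only total LYL is available (aggregated inputs
#' carry all-cause mortality), and no bootstrap is offered since there is no
#' individual resampling unit.
#'
#' @param agg an [aggregated_cohort()] for the diseased.
#' @param ref a [life_table()] for the reference population.
#' @param age_specific conditioning age (years).
#' @param tau restriction age; both tables must determine survival up to
#'   `tau`.
#' @return Object of class `lyl_agg_estimate` with `diseased_lyl`,
#'   `reference_lyl`, `excess`, the two life expectancies and the two
#'   conditional curves.
#' @export
lyl_aggregated <- function(agg, ref, age_specific, tau) {
  if (!inherits(agg, "lyl_aggregated_cohort")) {
    stop("agg must be an aggregated_cohort()")
  }
  if (!inherits(ref, "lyl_lifetable")) stop("ref must be a life_table()")
  pd <- lifetable_survival(agg$lifetable, age_specific, tau)
  pr <- lifetable_survival(ref, age_specific, tau)
  le_d <- pexp_restricted_area(pd)
  le_r <- pexp_restricted_area(pr)
  structure(list(condition_age = age_specific, tau = tau,
                 diseased_le = le_d, reference_le = le_r,
                 diseased_lyl = (tau - age_specific) - le_d,
                 reference_lyl = (tau - age_specific) - le_r,
                 excess = le_r - le_d,
                 diseased_curve = pd, reference_curve = pr),
            class = "lyl_agg_estimate")
}

#' @export
print.lyl_agg_estimate <- function(x, ...) {
  cat(sprintf(
    "Excess Life Years Lost at age %g (tau = %g), aggregated data\n",
    x$condition_age, x$tau))
  cat(sprintf("  diseased LYL:  %6.2f years\n", x$diseased_lyl))
  cat(sprintf("  reference LYL: %6.2f years\n", x$reference_lyl))
  cat(sprintf("  excess:        %6.2f years\n", x$excess))
  invisible(x)
}

#' @export
summary.lyl_agg_estimate <- function(object, ...) print(object, ...)

#' @export
plot.lyl_agg_estimate <- function(x, ...) {
  grid <- seq(x$condition_age, x$tau, length.out = 201)
  df <- rbind(
    data.frame(age = grid, surv = pexp_value(x$diseased_curve, grid),
               panel = "diseased"),
    data.frame(age = grid, surv = pexp_value(x$reference_curve, grid),
               panel = "reference"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$surv, ymax = 1),
                         fill = "grey55", alpha = 0.75) +
    ggplot2::geom_line(ggplot2::aes(y = .data$surv)) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "Age (years)", y = "Probability") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}

#' Onset-weighted excess Life Years Lost from aggregated data
#'
#' Computes the per-age excess LYL ([lyl_aggregated()]) at every integer age
#' in `[age_begin, age_end]` and averages it over the observed age-at-onset
#' distribution given by the table's new-case counts.
#'
#' @inheritParams lyl_aggregated
#' @param age_begin,age_end integer conditioning-age range (inclusive; the
#'   count at `age_begin` itself is included in the weights).
#' @return Object of class `lyl_agg_summary` with the weighted diseased and
#'   reference life expectancies, LYL, the weighted `excess`, and the
#'   per-age table.
#' @export
lyl_aggregated_range <- function(agg, ref, age_begin, age_end, tau) {
  if (age_begin > age_end) stop("age_begin must not exceed age_end")
  if (age_end >= tau) stop("age_end must be below tau")
  ages <- seq(age_begin, age_end)
  pos <- match(ages, agg$age)
  if (anyNA(pos)) stop("age range not covered by the aggregated table")
  w <- agg$new_cases[pos]
  if (sum(w) <= 0) stop("all new-case counts are zero in the age range")
  per_age <- lapply(ages, function(a) lyl_aggregated(agg, ref, a, tau))
  tab <- data.frame(
    age = ages,
    new_cases = w,
    diseased_le = vapply(per_age, `[[`, numeric(1), "diseased_le"),
    reference_le = vapply(per_age, `[[`, numeric(1), "reference_le"),
    diseased_lyl = vapply(per_age, `[[`, numeric(1), "diseased_lyl"),
    reference_lyl = vapply(per_age, `[[`, numeric(1), "reference_lyl"),
    excess = vapply(per_age, `[[`, numeric(1), "excess")
  )
  wn <- w / sum(w)
  structure(list(age_range = c(age_begin, age_end), tau = tau,
                 n_cases = sum(w),
                 diseased_le = sum(wn * tab$diseased_le),
                 reference_le = sum(wn * tab$reference_le),
                 diseased_lyl = sum(wn * tab$diseased_lyl),
                 reference_lyl = sum(wn * tab$reference_lyl),
                 excess = sum(wn * tab$excess),
                 table = tab),
            class = "lyl_agg_summary")
}

#' @export
print.lyl_agg_summary <- function(x, ...) {
  cat(sprintf(
    "Excess Life Years Lost over onset ages %d-%d (tau = %g), %g cases\n",
    x$age_range[1], x$age_range[2], x$tau, x$n_cases))
  cat(sprintf("  weighted diseased LYL:  %6.2f years\n", x$diseased_lyl))
  cat(sprintf("  weighted reference LYL: %6.2f years\n", x$reference_lyl))
  cat(sprintf("  weighted excess:        %6.2f years\n", x$excess))
  invisible(x)
}

#' @export
summary.lyl_agg_summary <- function(object, ...) print(object, ...)

#' Tabulate a cohort into an aggregated age-indexed table
#'
#' Occurrence/exposure tabulation: for each one-year age interval the
#' mortality rate is deaths divided by person-years at risk, and new cases
#' are counted from the onset column (floor binning). This is the bridge
#' from individual-level data to the aggregated mode, and at large cohort
#' sizes the aggregated estimate converges to the individual-level one.
#'
#' @param cohort an [lyl_cohort()].
#' @param age_min,age_max integer bounds of the tabulation (rates cover
#'   `[age_min, age_max)`, one row per year).
#' @return An [aggregated_cohort()]. If the cohort has no onset column (or
#'   no onsets fall in the range) the new-case counts are set to 1 per age,
#'   i.e. uniform weights, since the aggregated container requires a
#'   positive weight total.
#' @export
aggregate_cohort <- function(cohort, age_min = 0,
                             age_max = ceiling(max(cohort$exit))) {
  ages <- seq(age_min, age_max - 1)
  cl <- cohort_censor(cohort)
  dead <- cohort$status != cl
  rate <- vapply(ages, function(x) {
    py <- sum(pmax(0, pmin(cohort$exit, x + 1) - pmax(cohort$entry, x)))
    if (py == 0) return(0)
    sum(dead & cohort$exit >= x & cohort$exit < x + 1) / py
  }, numeric(1))
  cases <- numeric(length(ages))
  if (!is.null(cohort$onset)) {
    on <- floor(cohort$onset[!is.na(cohort$onset)])
    on <- on[on >= age_min & on < age_max]
    cases <- tabulate(on - age_min + 1L, nbins = length(ages))
  }
  if (sum(cases) == 0) cases <- rep(1, length(ages))  # uniform placeholder
  aggregated_cohort(ages, rate = rate, new_cases = cases)
}
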