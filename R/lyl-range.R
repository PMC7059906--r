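#' Life Years Lost at each integer age over a range
#'
#' Repeats [lyl_at_age()] at every integer conditioning age in
#' `[age_begin, age_end]`, sharing one pass over the cohort. Ages where no
#' individual is ever at risk yield a flagged missing row rather than an
#' error, so sparse old ages do not abort a whole range run.
#'
#' @param cohort an [lyl_cohort()].
#' @param age_begin,age_end integer conditioning ages, `age_begin <= age_end
#'   < tau`.
#' @param tau restriction age (years).
#' @return An object of class `lyl_table`: a data.frame with one row per
#'   age and columns `age`, `n_at_risk`, `life_exp`, `lyl_total`, one
#'   `lyl_<cause>` column per cause and a logical `missing` flag; attributes
#'   `tau`, `cause_labels` and the cohort (for bootstrapping).
#' @export
lyl_over_range <- function(cohort, age_begin, age_end, tau = 95) {
  if (!inherits(cohort, "lyl_cohort")) stop("cohort must be an lyl_cohort")
  if (age_begin != floor(age_begin) || age_end != floor(age_end)) {
    stop("age_begin and age_end must be integers")
  }
  if (age_begin > age_end) stop("age_begin must not exceed age_end")
  if (age_end >= tau) stop("age_end must be below tau")
  prep <- aj_prepare(cohort)
  ages <- seq(age_begin, age_end)
  tab <- range_core(prep, cohort, ages, tau)
  attr(tab, "tau") <- tau
  attr(tab, "cause_labels") <- cohort_causes(cohort)
  attr(tab, "cohort") <- cohort
  class(tab) <- c("lyl_table", "data.frame")
  tab
}

# Numeric core shared with the bootstrap: one prepared cohort, many ages.
range_core <- function(prep, cohort, ages, tau) {
  causes <- prep$causes
  q <- 2L + length(causes)
  m <- matrix(NA_real_, length(ages), q)
  miss <- logical(length(ages))
  for (i in seq_along(ages)) {
    a <- ages[i]
    fit <- tryCatch(aj_fit(prep, a), error = function(e) NULL)
    if (is.null(fit)) {
      miss[i] <- TRUE
      next
    }
    crv <- new_stepcurve(a, fit$times, fit$surv, "survival")
    le <- restricted_area(crv, a, tau)
    by_cause <- vapply(seq_along(causes), function(k) {
      restricted_area(new_stepcurve(a, fit$times, fit$cif[, k], "cif"),
                      a, tau)
    }, numeric(1))
    m[i, ] <- c(le, (tau - a) - le, by_cause)
  }
  tab <- data.frame(
    age = ages,
    n_at_risk = vapply(ages, function(a) {
      sum(cohort$entry <= a & a < cohort$exit)
    }, numeric(1))
  )
  tab$life_exp <- m[, 1]
  tab$lyl_total <- m[, 2]
  for (k in seq_along(causes)) {
    tab[[paste0("lyl_", causes[k])]] <- m[, 2L + k]
  }
  tab$missing <- miss
  tab
}

#' Onset-count weights for range summaries
#'
#' Bins observed disease-onset ages into integer conditioning ages by
#' flooring (an onset at 45.9 years counts at age 45), giving the number of
#' new cases per age used to weight per-age estimates into one overall
#' summary.
#'
#' @param onset_ages numeric vector of onset ages; all must lie in
#'   `[age_begin, age_end + 1)`.
#' @param age_begin,age_end integer age range of the target table.
#' @return An object of class `lyl_weights`: named integer counts for every
#'   age in the range (zeros kept).
#' @export
weights_from_onsets <- function(onset_ages, age_begin, age_end) {
  onset_ages <- onset_ages[!is.na(onset_ages)]
  if (!length(onset_ages)) stop("no onset ages supplied")
  bad <- onset_ages < age_begin | onset_ages >= age_end + 1
  if (any(bad)) {
    stop("onset age(s) outside [", age_begin, ", ", age_end + 1, "): ",
         paste(utils::head(sort(onset_ages[bad]), 10L), collapse = ", "))
  }
  ages <- seq(age_begin, age_end)
  cnt <- tabulate(floor(onset_ages) - age_begin + 1L, nbins = length(ages))
  structure(stats::setNames(cnt, ages), class = "lyl_weights",
            age_begin = age_begin, age_end = age_end)
}

#' Onset-weighted overall summary of a per-age LYL table
#'
#' Averages the per-age restricted life expectancies and Life Years Lost
#' over the observed age-at-onset distribution: each quantity becomes
#' \eqn{\sum_i n_i x_i / \sum_i n_i} with \eqn{n_i} the number of new cases
#' at age i. The result is the expected remaining life (and life lost
#' before tau) for a randomly drawn new case.
#'
#' @param x an `lyl_table` (or a bootstrapped one, see [lyl_boot()]).
#' @param weights an [weights_from_onsets()] object, or a numeric vector of
#'   raw onset ages (converted with the table's range).
#' @param ... unused.
#' @return For a plain table, an object of class `lyl_summary` with the
#'   weighted `life_exp`, `lyl_total`, `lyl_by_cause`, the weight total and
#'   the weighted restriction horizon `sum n_i (tau - i) / sum n_i`.
#' @export
weighted_summary <- function(x, weights, ...) UseMethod("weighted_summary")

resolve_weights <- function(weights, tab) {
  if (!inherits(weights, "lyl_weights")) {
    weights <- weights_from_onsets(weights, min(tab$age), max(tab$age))
  }
  w_age <- as.integer(names(weights))
  if (!all(w_age %in% tab$age)) {
    stop("weights refer to ages outside the table")
  }
  pos <- match(w_age, tab$age)
  if (any(weights > 0 & tab$missing[pos])) {
    stop("positive weight on age(s) with no estimate: ",
         paste(w_age[weights > 0 & tab$missing[pos]], collapse = ", "))
  }
  if (sum(weights) <= 0) stop("weights must have a positive total")
  list(age = w_age, w = as.numeric(weights), pos = pos)
}

#' @rdname weighted_summary
#' @export
weighted_summary.lyl_table <- function(x, weights, ...) {
  rw <- resolve_weights(weights, x)
  w <- rw$w / sum(rw$w)
  causes <- attr(x, "cause_labels")
  tau <- attr(x, "tau")
  by_cause <- vapply(causes, function(k) {
    sum(w * x[[paste0("lyl_", k)]][rw$pos])
  }, numeric(1))
  structure(list(
    tau = tau,
    age_range = range(x$age),
    horizon = sum(w * (tau - rw$age)),
    life_exp = sum(w * x$life_exp[rw$pos]),
    lyl_total = sum(w * x$lyl_total[rw$pos]),
    lyl_by_cause = by_cause,
    n_cases = sum(rw$w)
  ), class = "lyl_summary")
}

#' @export
print.lyl_summary <- function(x, ...) {
  cat(sprintf(
    "Life Years Lost averaged over onset ages %d-%d (tau = %g), %g cases\n",
    x$age_range[1], x$age_range[2], x$tau, x$n_cases))
  cat(sprintf("  weighted remaining life expectancy: %.1f years\n",
              x$life_exp))
  cat(sprintf("  weighted total life lost:           %.1f years\n",
              x$lyl_total))
  for (k in names(x$lyl_by_cause)) {
    cat(sprintf("    due to %-12s %.1f years\n", paste0(k, ":"),
                x$lyl_by_cause[[k]]))
  }
  invisible(x)
}

#' @export
print.lyl_table <- function(x, digits = 2, ...) {
  cat(sprintf("Per-age Life Years Lost, ages %d-%d, tau = %g\n",
              min(x$age), max(x$age), attr(x, "tau")))
  print.data.frame(round_df(as.data.frame(x), digits), row.names = FALSE)
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' @export
summary.lyl_table <- function(object, weights = NULL, ...) {
  if (is.null(weights)) return(print(object, ...))
  weighted_summary(object, weights)
}
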