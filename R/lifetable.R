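#' Reference life table
#'
#' A life table gives, for consecutive integer ages, the proportion of the
#' population still alive at that exact age and/or the age-specific
#' mortality rate on the following one-year interval. Either column alone is
#' sufficient: rates are recovered from survivor ratios as
#' `rate(x) = -log(S(x+1)/S(x))`, and survivor proportions from rates by
#' `S(x+1) = S(x) exp(-rate(x))` (the piecewise-exponential, i.e. constant
#' hazard within year, convention). When both columns are present they must
#' agree to within `tol`; the survivor column is then used.
#'
#' @param age integer vector of consecutive ages.
#' @param survivor optional survivor proportions at each exact age;
#'   non-increasing; normalized to the first value if it is not 1.
#' @param rate optional mortality rates (per person-year) on `[x, x + 1)`.
#' @param tol consistency tolerance between the two columns.
#' @return Object of class `lyl_lifetable` with elements `age`, `survivor`,
#'   `rate` (rate for the last year is `NA` when only survivor proportions
#'   were given) and `max_age`, the largest age up to which survival is
#'   determined.
#' @export
life_table <- function(age, survivor = NULL, rate = NULL, tol = 1e-6) {
  if (is.null(survivor) && is.null(rate)) {
    stop("at least one of survivor and rate must be provided")
  }
  if (anyNA(age) || any(age != floor(age))) stop("ages must be integers")
  if (length(age) < 2) stop("life table needs at least two ages")
  if (any(diff(age) != 1)) stop("ages must be consecutive integers")
  m <- length(age)
  if (!is.null(survivor)) {
    if (length(survivor) != m) stop("survivor must match age in length")
    if (anyNA(survivor) || any(survivor < 0)) {
      stop("survivor proportions must be non-negative")
    }
    if (any(diff(survivor) > 0)) {
      stop("survivor column must be non-increasing")
    }
    if (survivor[1] <= 0) stop("survivor proportion at the first age is 0")
    survivor <- survivor / survivor[1]
  }
  if (!is.null(rate)) {
    if (length(rate) != m) stop("rate must match age in length")
    if (anyNA(rate) || any(rate < 0)) stop("rates must be non-negative")
  }
  if (!is.null(survivor) && !is.null(rate)) {
    ratio <- survivor[-1] / survivor[-m]
    ratio[is.nan(ratio)] <- 0
    bad <- abs(ratio - exp(-rate[-m])) > tol
    if (any(bad)) {
      stop("survivor and rate columns are inconsistent at age(s) ",
           paste(utils::head(age[-m][bad], 10L), collapse = ", "),
           ": |S(x+1)/S(x) - exp(-rate(x))| exceeds ", tol)
    }
  }
  if (is.null(survivor)) {
    survivor <- c(1, exp(-cumsum(rate[-m])))
    max_age <- age[m] + 1
  } else if (is.null(rate)) {
    ratio <- survivor[-1] / survivor[-m]
    r <- -log(ratio)
    r[survivor[-m] == 0] <- Inf
    rate <- c(r, NA_real_)
    max_age <- age[m]
  } else {
    max_age <- age[m] + 1
  }
  structure(list(age = as.integer(age), survivor = survivor, rate = rate,
                 max_age = max_age),
            class = "lyl_lifetable")
}

#' @export
print.lyl_lifetable <- function(x, ...) {
  cat(sprintf("Life table, ages %d-%d (survival determined up to age %g)\n",
              x$age[1], x$age[length(x$age)], x$max_age))
  invisible(x)
}

# Survivor proportion at an arbitrary (fractional) age, with exponential
# interpolation within years.
lifetable_survivor_at <- function(lt, t) {
  i <- findInterval(t, lt$age)
  if (any(t < lt$age[1]) || any(t > lt$max_age)) {
    stop("age outside the life-table span")
  }
  m <- length(lt$age)
  s <- numeric(length(t))
  for (j in seq_along(t)) {
    if (i[j] >= m) { # in the final year covered by a rate, or at max_age
      if (t[j] == lt$age[m]) {
        s[j] <- lt$survivor[m]
      } else {
        s[j] <- lt$survivor[m] * exp(-lt$rate[m] * (t[j] - lt$age[m]))
      }
    } else {
      dt <- t[j] - lt$age[i[j]]
      r <- -log(lt$survivor[i[j] + 1] / lt$survivor[i[j]])
      if (lt$survivor[i[j]] == 0) {
        s[j] <- 0
      } else if (dt == 0) {
        s[j] <- lt$survivor[i[j]]
      } else {
        s[j] <- lt$survivor[i[j]] * exp(-r * dt)
      }
    }
  }
  s
}

#' Conditional piecewise-exponential survival from a life table
#'
#' Builds the survival curve for an individual alive at `condition_age`,
#' assuming a constant hazard within each year of age (so survival decays
#' exponentially between integer ages). Fractional conditioning ages are
#' handled by the within-year exponential.
#'
#' @param lt an [life_table()].
#' @param condition_age conditioning age (years); may be fractional.
#' @param tau restriction age; must not exceed the table's `max_age`.
#' @return Object of class `lyl_pexp`: knots (ages), conditional survivor
#'   values at the knots and per-segment rates, for use with
#'   [pexp_restricted_area()] and [pexp_value()].
#' @export
lifetable_survival <- function(lt, condition_age, tau) {
  if (condition_age >= tau) stop("condition_age must be below tau")
  if (condition_age < lt$age[1]) {
    stop("condition_age is below the life-table span")
  }
  if (tau > lt$max_age) {
    stop("tau (", tau, ") is beyond the last age (", lt$max_age,
         ") determined by the life table")
  }
  knots <- unique(c(condition_age,
                    lt$age[lt$age > condition_age & lt$age < tau], tau))
  s_abs <- lifetable_survivor_at(lt, knots)
  s0 <- s_abs[1]
  if (s0 <= 0) stop("no survivors at the conditioning age in the life table")
  s <- s_abs / s0
  nseg <- length(knots) - 1
  w <- diff(knots)
  r <- numeric(nseg)
  for (i in seq_len(nseg)) {
    if (s[i] == 0) {
      r[i] <- Inf
    } else if (s[i + 1] == 0) {
      r[i] <- Inf
    } else {
      r[i] <- -log(s[i + 1] / s[i]) / w[i]
    }
  }
  structure(list(knots = knots, surv = s, rate = r,
                 condition_age = condition_age, tau = tau),
            class = "lyl_pexp")
}

#' Restricted area under a piecewise-exponential survival curve
#'
#' Exact closed-form area: a segment of width w starting with survival s and
#' constant hazard r contributes `s (1 - exp(-r w)) / r` years (s w when
#' r = 0, and 0 when r is infinite).
#'
#' @param p an `lyl_pexp` from [lifetable_survival()].
#' @return Area in years between the conditioning age and tau.
#' @export
pexp_restricted_area <- function(p) {
  w <- diff(p$knots)
  s <- p$surv[-length(p$surv)]
  r <- p$rate
  seg <- ifelse(r == 0, s * w,
                ifelse(is.infinite(r), 0, s * (1 - exp(-r * w)) / r))
  sum(seg)
}

#' Evaluate a piecewise-exponential survival curve
#'
#' @param p an `lyl_pexp`.
#' @param t ages within `[condition_age, tau]`.
#' @return Conditional survival values.
#' @export
pexp_value <- function(p, t) {
  if (any(t < p$condition_age | t > p$tau)) {
    stop("t outside the curve's range")
  }
  i <- pmin(findInterval(t, p$knots), length(p$knots) - 1)
  dt <- t - p$knots[i]
  out <- p$surv[i] * exp(-p$rate[i] * dt)
  out[dt == 0] <- p$surv[i][dt == 0]
  out
}

#' Life Years Lost before tau implied by a life table
#'
#' Convenience wrapper: `tau - condition_age` minus the restricted area of
#' the conditional piecewise-exponential survival curve.
#'
#' @inheritParams lifetable_survival
#' @return LYL in years.
#' @export
lifetable_lyl <- function(lt, condition_age, tau) {
  (tau - condition_age) -
    pexp_restricted_area(lifetable_survival(lt, condition_age, tau))
}
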