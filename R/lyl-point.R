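#' Life Years Lost at one specific age
#'
#' Estimates the tau-restricted remaining life expectancy for individuals at
#' risk at `condition_age`, and the complementary Life Years Lost (LYL)
#' before age `tau`, decomposed into causes of death. The survivor curve is
#' the landmark-conditioned product-limit estimator, the cause decomposition
#' is Aalen-Johansen, and the restricted life expectancy is the area under
#' the conditional survivor curve from `condition_age` to `tau`:
#' \deqn{LE = \int_a^\tau S(t \mid a)\,dt, \qquad
#'       LYL = (\tau - a) - LE = \sum_k \int_a^\tau F_k(t \mid a)\,dt.}
#' Identically, each cause's LYL is the area of its band in the stacked-CIF
#' plot, so the total always equals the sum over causes.
#'
#' @param cohort an [lyl_cohort()]. For a diseased population the entry age
#'   should be the onset age (see [onset_cohort()]) so that follow-up starts
#'   at diagnosis.
#' @param condition_age conditioning (landmark) age a, in years.
#' @param tau restriction age (years), `> condition_age`. LYL is
#'   interpretable as life lost after `condition_age` and before `tau`; with
#'   administrative censoring `tau` should not exceed the censoring age.
#' @return An object of class `lyl_estimate`: a list with
#'   `condition_age`, `tau`, `life_exp` (restricted remaining life
#'   expectancy), `lyl_total`, `lyl_by_cause` (named numeric),
#'   `n_at_risk` (risk-set size at the conditioning age), and the fitted
#'   `curves` (an `lyl_crcurves`). The cohort is kept for bootstrapping.
#' @examples
#' ch <- lyl_cohort(0, c(50, 60, 70, 96), c("dead", "dead", "dead", "alive"))
#' lyl_at_age(ch, 45, tau = 95)
#' @export
lyl_at_age <- function(cohort, condition_age, tau = 95) {
  if (!inherits(cohort, "lyl_cohort")) stop("cohort must be an lyl_cohort")
  if (condition_age >= tau) stop("condition_age must be below tau")
  fit <- fit_competing_risks(cohort, condition_age)
  est <- lyl_from_curves(fit, condition_age, tau)
  est$n_at_risk <- sum(cohort$entry <= condition_age &
                         condition_age < cohort$exit)
  est$curves <- fit
  est$cohort <- cohort
  class(est) <- "lyl_estimate"
  est
}

# Shared numeric core: restricted areas from fitted curves.
lyl_from_curves <- function(fit, condition_age, tau) {
  le <- restricted_area(fit$survival, condition_age, tau)
  by_cause <- vapply(fit$cifs, restricted_area, numeric(1),
                     from_age = condition_age, to_age = tau)
  list(condition_age = condition_age, tau = tau, life_exp = le,
       lyl_total = (tau - condition_age) - le, lyl_by_cause = by_cause)
}

lyl_quantities <- function(est) {
  c(life_exp = est$life_exp, lyl_total = est$lyl_total,
    stats::setNames(est$lyl_by_cause,
                    paste0("lyl_", names(est$lyl_by_cause))))
}

#' @export
print.lyl_estimate <- function(x, ...) {
  cat(sprintf(
    "Life Years Lost at age %g (restricted to age %g)\n", x$condition_age,
    x$tau))
  cat(sprintf("  individuals at risk at age %g: %d\n", x$condition_age,
              x$n_at_risk))
  cat(sprintf("  remaining life expectancy: %.1f years\n", x$life_exp))
  cat(sprintf("  total life lost:           %.1f years\n", x$lyl_total))
  for (k in names(x$lyl_by_cause)) {
    cat(sprintf("    due to %-12s %.1f years\n", paste0(k, ":"),
                x$lyl_by_cause[[k]]))
  }
  invisible(x)
}

#' @export
summary.lyl_estimate <- function(object, ...) print(object, ...)

#' Stacked survival / cumulative-incidence plot data
#'
#' Extracts the series of the stacked plot: the conditional survivor curve
#' S(t), then S(t) + F_1(t), S(t) + F_1(t) + F_2(t), ... with causes in
#' their cohort order. The topmost series is identically 1, so the bands
#' between consecutive series partition the probability into "alive" and
#' per-cause "dead" regions whose areas over `[a, tau]` are the restricted
#' life expectancy and the cause-specific LYL.
#'
#' @param x an `lyl_estimate` (or an `lyl_crcurves` with `tau` supplied).
#' @param tau upper age for the grid; defaults to the estimate's `tau`.
#' @return A data.frame with columns `age`, `series` (factor: `"survival"`
#'   then the cause labels) and `value` (the cumulative stacked bound,
#'   right-continuous in `age`).
#' @export
lyl_stacked_data <- function(x, tau = NULL) {
  if (inherits(x, "lyl_estimate")) {
    curves <- x$curves
    if (is.null(tau)) tau <- x$tau
  } else if (inherits(x, "lyl_crcurves")) {
    curves <- x
    if (is.null(tau)) stop("tau must be supplied for raw curves")
  } else {
    stop("x must be an lyl_estimate or lyl_crcurves")
  }
  a <- curves$condition_age
  j <- curves$survival$jump_ages
  grid <- unique(c(a, j[j <= tau], tau))
  s <- stepcurve_value(curves$survival, grid)
  out <- data.frame(age = grid, series = "survival", value = s)
  acc <- s
  for (k in names(curves$cifs)) {
    acc <- acc + stepcurve_value(curves$cifs[[k]], grid)
    out <- rbind(out, data.frame(age = grid, series = k, value = acc))
  }
  out$series <- factor(out$series, levels = c("survival",
                                              names(curves$cifs)))
  out
}

# Duplicate each jump so geom_ribbon draws proper right-continuous steps.
step_expand <- function(df) {
  or <- order(df$series, df$age)
  df <- df[or, , drop = FALSE]
  out <- do.call(rbind, lapply(split(df, df$series), function(d) {
    n <- nrow(d)
    if (n < 2L) return(d)
    data.frame(age = c(d$age[1], rep(d$age[-1], each = 2L)),
               series = d$series[1],
               value = c(rep(d$value[-n], each = 2L), d$value[n]))
  }))
  rownames(out) <- NULL
  out
}

#' @export
plot.lyl_estimate <- function(x, colors = NULL, ...) {
  long <- step_expand(lyl_stacked_data(x))
  wide <- split(long, long$series)
  lower <- wide[["survival"]]
  bands <- NULL
  prev <- lower$value
  for (k in names(x$lyl_by_cause)) {
    cur <- wide[[k]]$value
    bands <- rbind(bands, data.frame(age = lower$age, ymin = prev,
                                     ymax = cur, cause = k))
    prev <- cur
  }
  bands$cause <- factor(bands$cause, levels = names(x$lyl_by_cause))
  p <- ggplot2::ggplot(bands, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ymin, ymax = .data$ymax,
                                      fill = .data$cause), alpha = 0.75) +
    ggplot2::geom_step(data = data.frame(age = lower$age, s = lower$value),
                       ggplot2::aes(y = .data$s)) +
    ggplot2::labs(x = "Age (years)", y = "Probability",
                  fill = "Cause of death") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
  if (!is.null(colors)) p <- p + ggplot2::scale_fill_manual(values = colors)
  p
}
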