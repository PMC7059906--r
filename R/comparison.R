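#' Excess Life Years Lost: diseased cohort versus a reference cohort
#'
#' Compares two LYL results at the same conditioning age (or over the same
#' age range, weighted by new cases) and reports the difference
#' `diseased - reference` for total and cause-specific Life Years Lost,
#' together with the equal-magnitude deficit in restricted life expectancy.
#' Either side may carry bootstrap replicates ([lyl_boot()]); a side without
#' them is treated as estimated without uncertainty. If both sides are
#' bootstrapped they must use the same number of iterations and are paired
#' by iteration index.
#'
#' @param diseased,reference each an `lyl_estimate`, `lyl_table` or
#'   `lyl_boot` thereof. Tables require `weights`.
#' @param weights onset weights ([weights_from_onsets()] or raw onset ages)
#'   applied to both sides when comparing range tables.
#' @param level confidence level for difference CIs when replicates exist.
#' @return Object of class `lyl_excess` with `lyl_diff` (named: total then
#'   per cause when the cause sets match), `le_diff`
#'   (reference life expectancy minus diseased, equal to the total), `ci`
#'   (when available), plus the two collapsed sides.
#' @export
excess_lyl <- function(diseased, reference, weights = NULL, level = 0.95) {
  d <- collapse_side(diseased, weights)
  r <- collapse_side(reference, weights)
  if (!isTRUE(all.equal(d$tau, r$tau))) stop("tau differs between sides")
  if (!is.na(d$condition_age) && !is.na(r$condition_age) &&
      d$condition_age != r$condition_age) {
    stop("conditioning ages differ between sides")
  }
  same_causes <- identical(names(d$lyl_by_cause), names(r$lyl_by_cause))
  diff_point <- c(total = d$lyl_total - r$lyl_total)
  if (same_causes) {
    diff_point <- c(diff_point, d$lyl_by_cause - r$lyl_by_cause)
  }
  ci <- diff_ci(d, r, names(diff_point), level)
  structure(list(lyl_diff = diff_point,
                 le_diff = r$life_exp - d$life_exp,
                 ci = ci, level = level,
                 diseased = d, reference = r),
            class = "lyl_excess")
}

# Collapse any accepted input to a flat list of point quantities plus an
# optional replicate matrix with columns lyl_total / lyl_<cause> / life_exp.
collapse_side <- function(x, weights) {
  if (inherits(x, "lyl_boot")) {
    if (x$kind == "range") {
      if (is.null(weights)) {
        stop("weights are required to compare range results")
      }
      x <- weighted_summary(x, weights)
    }
    point <- x$point
    flat <- collapse_side(point, weights)
    flat$replicates <- x$replicates
    flat$niter <- x$niter
    return(flat)
  }
  if (inherits(x, "lyl_table")) {
    if (is.null(weights)) stop("weights are required to compare range results")
    x <- weighted_summary(x, weights)
  }
  if (inherits(x, "lyl_summary")) {
    return(list(condition_age = NA_real_, tau = x$tau,
                life_exp = x$life_exp, lyl_total = x$lyl_total,
                lyl_by_cause = x$lyl_by_cause, replicates = NULL))
  }
  if (inherits(x, "lyl_estimate")) {
    return(list(condition_age = x$condition_age, tau = x$tau,
                life_exp = x$life_exp, lyl_total = x$lyl_total,
                lyl_by_cause = x$lyl_by_cause, replicates = NULL))
  }
  stop("unsupported input of class ", paste(class(x), collapse = "/"))
}

# Percentile CI for differences, treating a replicate-free side as fixed.
diff_ci <- function(d, r, qnames, level) {
  if (is.null(d$replicates) && is.null(r$replicates)) return(NULL)
  cols <- function(side, nm) {
    # replicate columns are life_exp, lyl_total, lyl_<cause>
    key <- ifelse(nm == "total", "lyl_total", paste0("lyl_", nm))
    side$replicates[, key, drop = FALSE]
  }
  point_vec <- function(side, nm) {
    ifelse(nm == "total", side$lyl_total, side$lyl_by_cause[nm])
  }
  reps <- vapply(qnames, function(nm) {
    dv <- if (is.null(d$replicates)) NULL else as.numeric(cols(d, nm))
    rv <- if (is.null(r$replicates)) NULL else as.numeric(cols(r, nm))
    if (!is.null(dv) && !is.null(rv)) {
      if (length(dv) != length(rv)) {
        stop("both sides bootstrapped with unequal niter")
      }
      dv - rv
    } else if (!is.null(dv)) {
      dv - point_vec(r, nm)
    } else {
      point_vec(d, nm) - rv
    }
  }, numeric(max(if (is.null(d$replicates)) 0 else d$niter,
                 if (is.null(r$replicates)) 0 else r$niter)))
  ci <- apply(reps, 2L, stats::quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  rownames(ci) <- c("lower", "upper")
  ci
}

#' @export
print.lyl_excess <- function(x, ...) {
  cat("Excess Life Years Lost (diseased minus reference)\n")
  for (nm in names(x$lyl_diff)) {
    if (!is.null(x$ci)) {
      cat(sprintf("  %-12s %6.2f years  (%g%% CI %.2f - %.2f)\n", nm,
                  x$lyl_diff[[nm]], 100 * x$level, x$ci["lower", nm],
                  x$ci["upper", nm]))
    } else {
      cat(sprintf("  %-12s %6.2f years\n", nm, x$lyl_diff[[nm]]))
    }
  }
  invisible(x)
}

#' Excess Life Years Lost against a standard life table
#'
#' Compares an individual-level diseased estimate with a reference
#' population given only as a life table (mortality rates and/or survivor
#' proportions). The reference LYL at each conditioning age comes from the
#' conditional piecewise-exponential survival implied by the table
#' ([lifetable_survival()]). Life tables carry no cause-of-death
#' information, so the comparison is total-only; the diseased side's cause
#' decomposition is reported alongside for context. The reference is
#' treated as estimated without uncertainty, so difference CIs use the
#' diseased replicates only.
#'
#' @param diseased an `lyl_estimate`, `lyl_table`, or `lyl_boot` thereof.
#' @param lt a [life_table()] spanning the conditioning ages up to tau.
#' @param weights onset weights, required for range inputs.
#' @param level confidence level for the difference CI.
#' @return Object of class `lyl_excess_ref`: `excess` (total, years),
#'   `reference_lyl`, `diseased_lyl`, `diseased_by_cause`, and `ci` when
#'   the diseased side has replicates.
#' @export
excess_lyl_vs_lifetable <- function(diseased, lt, weights = NULL,
                                    level = 0.95) {
  if (!inherits(lt, "lyl_lifetable")) stop("lt must be a life_table()")
  reps <- NULL
  if (inherits(diseased, "lyl_boot")) {
    if (diseased$kind == "range") {
      if (is.null(weights)) stop("weights are required for range results")
      diseased <- weighted_summary(diseased, weights)
    }
    reps <- diseased$replicates[, "lyl_total"]
    point <- diseased$point
  } else {
    point <- diseased
  }
  if (inherits(point, "lyl_table")) {
    if (is.null(weights)) stop("weights are required for range results")
    point <- weighted_summary(point, weights)
  }
  if (inherits(point, "lyl_summary")) {
    if (!inherits(weights, "lyl_weights")) {
      weights <- weights_from_onsets(weights, point$age_range[1],
                                     point$age_range[2])
    }
    w_age <- as.integer(names(weights))
    w <- as.numeric(weights) / sum(weights)
    keep <- w > 0
    ref_lyl <- sum(w[keep] * vapply(w_age[keep], function(a) {
      lifetable_lyl(lt, a, point$tau)
    }, numeric(1)))
  } else if (inherits(point, "lyl_estimate")) {
    ref_lyl <- lifetable_lyl(lt, point$condition_age, point$tau)
  } else {
    stop("unsupported diseased input")
  }
  excess <- point$lyl_total - ref_lyl
  ci <- NULL
  if (!is.null(reps)) {
    ci <- stats::quantile(reps - ref_lyl,
                          probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
    names(ci) <- c("lower", "upper")
  }
  structure(list(excess = excess, reference_lyl = ref_lyl,
                 diseased_lyl = point$lyl_total,
                 diseased_by_cause = point$lyl_by_cause,
                 ci = ci, level = level, tau = point$tau),
            class = "lyl_excess_ref")
}

#' @export
print.lyl_excess_ref <- function(x, ...) {
  cat("Excess Life Years Lost versus life-table reference\n")
  cat(sprintf("  diseased LYL:  %6.2f years\n", x$diseased_lyl))
  cat(sprintf("  reference LYL: %6.2f years\n", x$reference_lyl))
  if (!is.null(x$ci)) {
    cat(sprintf("  excess:        %6.2f years  (%g%% CI %.2f - %.2f)\n",
                x$excess, 100 * x$level, x$ci["lower"], x$ci["upper"]))
  } else {
    cat(sprintf("  excess:        %6.2f years\n", x$excess))
  }
  invisible(x)
}

#' Side-by-side stacked-curve data for two estimates
#'
#' Extracts the stacked plot series for two single-age estimates (e.g.
#' diseased and general population) for a side-by-side display.
#'
#' @param x,y `lyl_estimate` objects sharing the conditioning age and tau.
#' @param labels panel labels.
#' @return Data.frame of stacked series with a `panel` column.
#' @export
lyl_compare_data <- function(x, y, labels = c("diseased", "reference")) {
  dx <- lyl_stacked_data(x)
  dy <- lyl_stacked_data(y)
  dx$panel <- labels[1]
  dy$panel <- labels[2]
  rbind(dx, dy)
}

#' @export
plot.lyl_excess <- function(x, ...) {
  stop("plot the underlying estimates with plot() / lyl_compare_data()")
}
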