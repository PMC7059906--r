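#' Non-parametric bootstrap confidence intervals for LYL estimates
#'
#' Resamples individuals (whole records, including entry, exit, status and
#' onset) with replacement, re-runs the estimator on each resample, and
#' reports percentile confidence intervals. Works on a single-age estimate
#' ([lyl_at_age()]) or a per-age table ([lyl_over_range()]); a bootstrapped
#' table can then be collapsed with [weighted_summary()], which propagates
#' the replicates through the weighting.
#'
#' Each iteration uses its own RNG seed derived deterministically from the
#' master `seed`, so results are reproducible and a run can be extended to
#' more iterations without changing the earlier replicates. An iteration
#' whose resample leaves an estimated age with an empty risk set is redrawn,
#' up to `max_retry` attempts.
#'
#' @param x an `lyl_estimate` or `lyl_table`.
#' @param niter number of bootstrap iterations (>= 2; the convention in this
#'   field is 1000).
#' @param level confidence level (default 0.95).
#' @param seed master integer seed.
#' @param max_retry redraw cap per iteration for degenerate resamples.
#' @return An object of class `lyl_boot` with elements `point` (the input),
#'   `kind` (`"point"` or `"range"`), `replicates` (a niter x quantity
#'   matrix, or for a range a niter x age x quantity array), `ci`
#'   (percentile bounds), `level`, `seed`, `niter`.
#' @export
lyl_boot <- function(x, niter = 1000, level = 0.95, seed = 1,
                     max_retry = 25) {
  if (niter < 2) stop("niter must be at least 2")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  UseMethod("lyl_boot")
}

boot_seed <- function(seed, i) (as.integer(seed) + i) %% 2147483647L

#' @export
lyl_boot.lyl_estimate <- function(x, niter = 1000, level = 0.95, seed = 1,
                                  max_retry = 25) {
  cohort <- x$cohort
  n <- nrow(cohort)
  qn <- names(lyl_quantities(x))
  reps <- matrix(NA_real_, niter, length(qn), dimnames = list(NULL, qn))
  for (i in seq_len(niter)) {
    set.seed(boot_seed(seed, i))
    est <- NULL
    for (try in seq_len(max_retry)) {
      idx <- sample.int(n, n, replace = TRUE)
      est <- tryCatch({
        prep <- aj_prepare_idx(cohort, idx)
        fit <- aj_fit(prep, x$condition_age)
        curves_from_fit(fit, x$condition_age, prep$causes)
      }, error = function(e) NULL)
      if (!is.null(est)) break
    }
    if (is.null(est)) {
      stop("bootstrap iteration ", i, " failed after ", max_retry,
           " redraws (empty risk set at age ", x$condition_age, ")")
    }
    q <- lyl_from_curves(est, x$condition_age, x$tau)
    reps[i, ] <- c(q$life_exp, q$lyl_total, q$lyl_by_cause)
  }
  ci <- apply(reps, 2L, stats::quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  rownames(ci) <- c("lower", "upper")
  structure(list(point = x, kind = "point", replicates = reps, ci = ci,
                 level = level, seed = seed, niter = niter),
            class = "lyl_boot")
}

# Resampled prepare: same layout as aj_prepare but for an index vector.
aj_prepare_idx <- function(cohort, idx) {
  cause <- cohort_cause_index(cohort)[idx]
  exit <- cohort$exit[idx]
  ox <- order(exit)
  list(entry_sorted = sort(cohort$entry[idx]),
       exit_sorted = exit[ox], cause_sorted = cause[ox],
       n = length(idx), causes = cohort_causes(cohort))
}

curves_from_fit <- function(fit, condition_age, causes) {
  cifs <- lapply(seq_along(causes), function(k) {
    new_stepcurve(condition_age, fit$times, fit$cif[, k], "cif")
  })
  names(cifs) <- causes
  list(survival = new_stepcurve(condition_age, fit$times, fit$surv,
                                "survival"),
       cifs = cifs, condition_age = condition_age)
}

#' @export
lyl_boot.lyl_table <- function(x, niter = 1000, level = 0.95, seed = 1,
                               max_retry = 25) {
  cohort <- attr(x, "cohort")
  tau <- attr(x, "tau")
  causes <- attr(x, "cause_labels")
  ages <- x$age
  need <- !x$missing  # ages estimated in the point table must stay estimable
  n <- nrow(cohort)
  qn <- c("life_exp", "lyl_total", paste0("lyl_", causes))
  reps <- array(NA_real_, c(niter, length(ages), length(qn)),
                dimnames = list(NULL, ages, qn))
  for (i in seq_len(niter)) {
    set.seed(boot_seed(seed, i))
    ok <- FALSE
    for (try in seq_len(max_retry)) {
      idx <- sample.int(n, n, replace = TRUE)
      prep <- aj_prepare_idx(cohort, idx)
      tab <- range_core(prep, cohort[idx, , drop = FALSE], ages, tau)
      if (!any(need & tab$missing)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("bootstrap iteration ", i, " failed after ", max_retry,
           " redraws (resample lost all individuals at some estimated age)")
    }
    reps[i, , ] <- as.matrix(tab[, c("life_exp", "lyl_total",
                                     paste0("lyl_", causes))])
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- apply(reps, c(2L, 3L), stats::quantile, probs = probs, names = FALSE,
              na.rm = TRUE)
  structure(list(point = x, kind = "range", replicates = reps, ci = ci,
                 level = level, seed = seed, niter = niter),
            class = "lyl_boot")
}

#' @export
print.lyl_boot <- function(x, ...) {
  if (x$kind == "point") {
    est <- x$point
    cat(sprintf(
      "Life Years Lost at age %g (tau = %g), %d bootstrap iterations\n",
      est$condition_age, est$tau, x$niter))
    q <- lyl_quantities(est)
    for (j in names(q)) {
      cat(sprintf("  %-14s %6.2f  (%g%% CI %.2f - %.2f)\n", j, q[[j]],
                  100 * x$level, x$ci["lower", j], x$ci["upper", j]))
    }
  } else if (x$kind == "range") {
    cat(sprintf(
      "Per-age Life Years Lost, ages %d-%d, %d bootstrap iterations\n",
      min(x$point$age), max(x$point$age), x$niter))
    cat("use weighted_summary(x, weights) for an overall estimate with CI\n")
  } else {
    q <- x$point_quantities
    cat(sprintf("Weighted Life Years Lost summary, %d bootstrap iterations\n",
                x$niter))
    for (j in names(q)) {
      cat(sprintf("  %-14s %6.2f  (%g%% CI %.2f - %.2f)\n", j, q[[j]],
                  100 * x$level, x$ci["lower", j], x$ci["upper", j]))
    }
  }
  invisible(x)
}

#' @export
summary.lyl_boot <- function(object, weights = NULL, ...) {
  if (!is.null(weights)) return(weighted_summary(object, weights))
  print(object, ...)
}

#' @rdname weighted_summary
#' @export
weighted_summary.lyl_boot <- function(x, weights, ...) {
  if (x$kind != "range") {
    stop("weighted_summary applies to bootstrapped range tables")
  }
  tab <- x$point
  point <- weighted_summary(tab, weights)
  rw <- resolve_weights(weights, tab)
  w <- rw$w / sum(rw$w)
  qn <- dimnames(x$replicates)[[3]]
  # weighted mean per replicate and quantity
  reps <- vapply(seq_along(qn), function(k) {
    as.numeric(matrix(x$replicates[, rw$pos, k], nrow = x$niter) %*% w)
  }, numeric(x$niter))
  colnames(reps) <- qn
  probs <- c((1 - x$level) / 2, 1 - (1 - x$level) / 2)
  ci <- apply(reps, 2L, stats::quantile, probs = probs, names = FALSE)
  rownames(ci) <- c("lower", "upper")
  pq <- c(life_exp = point$life_exp, lyl_total = point$lyl_total,
          stats::setNames(point$lyl_by_cause,
                          paste0("lyl_", names(point$lyl_by_cause))))
  structure(list(point = point, point_quantities = pq, kind = "summary",
                 replicates = reps, ci = ci, level = x$level,
                 seed = x$seed, niter = x$niter, weights = weights),
            class = "lyl_boot")
}

#' Bootstrap-iteration sufficiency diagnostic
#'
#' Recomputes the percentile interval using only the first m replicates for
#' m = 10, ..., niter. If the interval endpoints still drift in the last
#' stretch of iterations, more iterations are needed. The convergence flag
#' requires both endpoints to move less than `tol` years over the final 20%
#' of iterations.
#'
#' @param result an `lyl_boot` (point kind, or the result of
#'   [weighted_summary()] on a bootstrapped range).
#' @param quantity which column of the replicates to track (default
#'   `"lyl_total"`).
#' @param tol drift tolerance in years for the convergence flag.
#' @return An object of class `lyl_ci_stability`: data.frame of running
#'   endpoints (`iter`, `lower`, `upper`) with attributes `converged` and
#'   `tol`.
#' @export
ci_stability <- function(result, quantity = "lyl_total", tol = 0.05) {
  if (!inherits(result, "lyl_boot")) stop("result must be an lyl_boot")
  if (result$kind == "range") {
    stop("apply weighted_summary() first to reduce a range bootstrap")
  }
  if (result$niter < 10) stop("need at least 10 iterations")
  v <- result$replicates[, quantity]
  probs <- c((1 - result$level) / 2, 1 - (1 - result$level) / 2)
  ms <- 10:result$niter
  run <- t(vapply(ms, function(m) {
    stats::quantile(v[1:m], probs = probs, names = FALSE)
  }, numeric(2)))
  out <- data.frame(iter = ms, lower = run[, 1], upper = run[, 2])
  tail_part <- out[out$iter > 0.8 * result$niter, ]
  converged <- (max(tail_part$lower) - min(tail_part$lower) < tol) &&
    (max(tail_part$upper) - min(tail_part$upper) < tol)
  structure(out, converged = converged, tol = tol,
            quantity = quantity, class = c("lyl_ci_stability", "data.frame"))
}

#' @export
print.lyl_ci_stability <- function(x, ...) {
  cat(sprintf(
    "Running CI endpoints for %s over %d-%d iterations; converged: %s\n",
    attr(x, "quantity"), min(x$iter), max(x$iter), attr(x, "converged")))
  invisible(x)
}
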