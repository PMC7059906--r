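#' Construct a cohort for Life Years Lost estimation
#'
#' A cohort holds one record per individual: age at entry into follow-up
#' (birth, registration, or disease onset), age at exit (death or censoring),
#' and the terminal status. Status is either the censoring label or one of the
#' death-cause categories. Ages are continuous (fractional years allowed).
#'
#' @param entry numeric vector of entry ages (years, >= 0). A single value is
#'   recycled; the common case "followed from birth" is `entry = 0`.
#' @param exit numeric vector of exit ages (years); must exceed `entry`
#'   record-wise (zero-length intervals are rejected).
#' @param status character (or factor) vector: the censoring label or a
#'   death-cause category. A numeric 0/1 vector is accepted and mapped to
#'   censored / a single cause `"dead"`.
#' @param censor_label the reserved status string marking censored records.
#' @param cause_labels optional character vector fixing the order of death
#'   causes; defaults to the causes in order of first appearance.
#' @param onset optional numeric vector of disease-onset ages (`NA` for
#'   individuals who never experience the disease).
#'
#' @return A `data.frame` of class `lyl_cohort` with columns `entry`, `exit`,
#'   `status` and optionally `onset`, carrying `censor_label` and
#'   `cause_labels` attributes.
#' @seealso [lyl_at_age()], [lyl_over_range()], [read_cohort()]
#' @export
lyl_cohort <- function(entry, exit, status, censor_label = "alive",
                       cause_labels = NULL, onset = NULL) {
  if (is.numeric(status)) {
    bad <- !status %in% c(0, 1)
    if (any(bad)) {
      stop("numeric status must be 0 (censored) or 1 (dead); found: ",
           paste(unique(status[bad]), collapse = ", "))
    }
    status <- ifelse(status == 1, "dead", censor_label)
  }
  status <- as.character(status)
  n <- max(length(entry), length(exit), length(status))
  if (length(entry) == 1L) entry <- rep(entry, n)
  if (length(entry) != n || length(exit) != n || length(status) != n) {
    stop("entry, exit and status must have matching lengths")
  }
  if (n == 0L) stop("cohort must contain at least one record")
  if (!is.numeric(entry) || !is.numeric(exit)) {
    stop("entry and exit ages must be numeric")
  }
  if (anyNA(entry) || anyNA(exit) || any(!is.finite(entry)) ||
      any(!is.finite(exit))) {
    stop("entry and exit ages must be finite and non-missing")
  }
  if (any(entry < 0)) stop("entry ages must be >= 0")
  bad <- which(exit <= entry)
  if (length(bad)) {
    stop("exit age must exceed entry age; offending record(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  if (!is.character(censor_label) || length(censor_label) != 1L ||
      !nzchar(censor_label)) {
    stop("censor_label must be a single non-empty string")
  }
  if (is.null(cause_labels)) {
    cause_labels <- setdiff(unique(status), censor_label)
  }
  cause_labels <- as.character(cause_labels)
  if (anyDuplicated(cause_labels)) stop("cause_labels must be unique")
  if (any(!nzchar(cause_labels))) stop("cause_labels must be non-empty strings")
  if (censor_label %in% cause_labels) {
    stop("censor_label cannot also be a cause label")
  }
  unknown <- setdiff(unique(status), c(censor_label, cause_labels))
  if (length(unknown)) {
    stop("unknown status value(s): ", paste(unknown, collapse = ", "))
  }
  out <- data.frame(entry = as.numeric(entry), exit = as.numeric(exit),
                    status = status, stringsAsFactors = FALSE)
  if (!is.null(onset)) {
    if (length(onset) != n) stop("onset must have one value per record")
    if (any(!is.na(onset) & (onset < 0 | !is.finite(onset)))) {
      stop("onset ages must be finite and >= 0 (or NA)")
    }
    out$onset <- as.numeric(onset)
  }
  attr(out, "censor_label") <- censor_label
  attr(out, "cause_labels") <- cause_labels
  class(out) <- c("lyl_cohort", "data.frame")
  out
}

#' @export
print.lyl_cohort <- function(x, ...) {
  cl <- attr(x, "censor_label")
  cat("Cohort of", nrow(x), "individuals\n")
  cat("  deaths by cause:",
      paste(sprintf("%s=%d", attr(x, "cause_labels"),
                    vapply(attr(x, "cause_labels"),
                           function(k) sum(x$status == k), integer(1))),
            collapse = ", "), "\n")
  cat("  censored (", cl, "): ", sum(x$status == cl), "\n", sep = "")
  if (!is.null(x$onset)) {
    cat("  with disease onset recorded:", sum(!is.na(x$onset)), "\n")
  }
  invisible(x)
}

cohort_censor <- function(cohort) attr(cohort, "censor_label")
cohort_causes <- function(cohort) attr(cohort, "cause_labels")

#' Restrict a population to diseased individuals, entering at onset
#'
#' Selects the records with a recorded disease-onset age and sets their entry
#' age to the onset age, so that follow-up starts at diagnosis. This is the
#' delayed-entry construction that avoids immortal time bias: a person must
#' survive to onset to be diagnosed, so their pre-onset person-time cannot be
#' counted as time lived with the disease.
#'
#' @param cohort an [lyl_cohort()] with an `onset` column.
#' @return An `lyl_cohort` of the diseased individuals with `entry = onset`.
#' @export
onset_cohort <- function(cohort) {
  if (is.null(cohort$onset)) stop("cohort has no onset column")
  keep <- !is.na(cohort$onset)
  if (!any(keep)) stop("no individuals with a recorded disease onset")
  lyl_cohort(entry = cohort$onset[keep], exit = cohort$exit[keep],
             status = cohort$status[keep],
             censor_label = cohort_censor(cohort),
             cause_labels = cohort_causes(cohort),
             onset = cohort$onset[keep])
}

# Map status strings to integer codes: 0 = censored, k = k-th cause.
cohort_cause_index <- function(cohort) {
  idx <- match(cohort$status, cohort_causes(cohort))
  idx[is.na(idx)] <- 0L
  idx
}
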