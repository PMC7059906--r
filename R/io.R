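#' Read an individual-level cohort from delimited text
#'
#' Reads a delimited file with a header row and maps its columns onto the
#' cohort fields. Malformed rows are rejected with their line numbers (line
#' 1 is the header) rather than silently coerced, and a short ingestion
#' summary (size, deaths by cause, censored, diseased) is emitted at
#' message level so the input can be sanity-checked.
#'
#' @param path file path.
#' @param exit_col,status_col required column names for exit age and status.
#' @param entry_col optional entry-age column; when absent everyone is
#'   taken to enter at age 0 (followed from birth).
#' @param onset_col optional disease-onset-age column (empty cells = never
#'   diseased).
#' @param censor_label status value marking censored records; a numeric 0/1
#'   status column is mapped to censored/`"dead"`.
#' @param sep field separator (default comma).
#' @param quiet suppress the ingestion summary.
#' @return An [lyl_cohort()].
#' @export
read_cohort <- function(path, exit_col, status_col, entry_col = NULL,
                        onset_col = NULL, censor_label = "alive",
                        sep = ",", quiet = FALSE) {
  df <- read_delim_checked(path, sep)
  need <- c(exit_col, status_col, entry_col, onset_col)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("column(s) not found in ", path, ": ", paste(miss, collapse = ", "))
  }
  num_col <- function(col, allow_na = FALSE) {
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- is.na(v) & !(allow_na & (is.na(raw) | !nzchar(trimws(raw))))
    if (any(bad)) {
      stop("non-numeric value(s) in column '", col, "' at line(s) ",
           paste(utils::head(which(bad) + 1L, 10L), collapse = ", "))
    }
    v
  }
  exit <- num_col(exit_col)
  entry <- if (is.null(entry_col)) rep(0, nrow(df)) else num_col(entry_col)
  onset <- if (is.null(onset_col)) NULL else num_col(onset_col,
                                                     allow_na = TRUE)
  bad <- which(exit <= entry)
  if (length(bad)) {
    stop("exit age does not exceed entry age at line(s) ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "))
  }
  ch <- lyl_cohort(entry = entry, exit = exit, status = df[[status_col]],
                   censor_label = censor_label, onset = onset)
  if (!quiet) {
    cl <- cohort_censor(ch)
    causes <- cohort_causes(ch)
    message(sprintf(
      "read %d records from %s: %s; censored %d%s", nrow(ch), path,
      paste(sprintf("%s deaths %d", causes,
                    vapply(causes, function(k) sum(ch$status == k),
                           integer(1))), collapse = ", "),
      sum(ch$status == cl),
      if (!is.null(ch$onset)) {
        sprintf("; diseased %d", sum(!is.na(ch$onset)))
      } else ""))
  }
  ch
}

read_delim_checked <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!nrow(df)) stop("no data rows in ", path)
  df
}

#' Read a reference life table from delimited text
#'
#' @param path file path.
#' @param age_col age column name.
#' @param surv_col,rate_col survivor-proportion and/or mortality-rate
#'   column names (at least one required); when both are present they are
#'   checked for piecewise-exponential consistency.
#' @param sep field separator.
#' @return A [life_table()].
#' @export
read_lifetable <- function(path, age_col = "age", surv_col = NULL,
                           rate_col = NULL, sep = ",") {
  df <- read_delim_checked(path, sep)
  need <- c(age_col, surv_col, rate_col)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("column(s) not found in ", path, ": ", paste(miss, collapse = ", "))
  }
  life_table(age = df[[age_col]],
             survivor = if (is.null(surv_col)) NULL else df[[surv_col]],
             rate = if (is.null(rate_col)) NULL else df[[rate_col]])
}

#' Read an aggregated diseased-population table from delimited text
#'
#' @inheritParams read_lifetable
#' @param cases_col new-cases column name.
#' @return An [aggregated_cohort()].
#' @export
read_aggregated <- function(path, age_col = "age", rate_col = NULL,
                            surv_col = NULL, cases_col = "new_cases",
                            sep = ",") {
  df <- read_delim_checked(path, sep)
  need <- c(age_col, rate_col, surv_col, cases_col)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("column(s) not found in ", path, ": ", paste(miss, collapse = ", "))
  }
  aggregated_cohort(age = df[[age_col]],
                    rate = if (is.null(rate_col)) NULL else df[[rate_col]],
                    survivor = if (is.null(surv_col)) NULL else
                      df[[surv_col]],
                    new_cases = df[[cases_col]])
}

#' Write machine- and human-readable reports of LYL results
#'
#' Serializes a result to JSON (always; machine-readable, includes the
#' confidence level, seed and iteration count when the result is
#' bootstrapped) and, for tabular results, to CSV in the standard per-age
#' layout (cases, life expectancy, life lost, per-cause columns).
#'
#' @param x an `lyl_estimate`, `lyl_boot`, `lyl_table`, `lyl_summary`,
#'   `lyl_excess`, `lyl_excess_ref`, `lyl_agg_estimate` or
#'   `lyl_agg_summary`.
#' @param json_path path for the JSON report (`NULL` to skip).
#' @param csv_path path for the CSV table (`NULL` to skip; only meaningful
#'   for per-age results).
#' @return Invisibly, the list that was serialized to JSON.
#' @export
write_report <- function(x, json_path = NULL, csv_path = NULL) {
  payload <- report_payload(x)
  if (!is.null(json_path)) {
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    tab <- report_table(x)
    if (is.null(tab)) {
      stop("no per-age table available for CSV output from class ",
           paste(class(x), collapse = "/"))
    }
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  invisible(payload)
}

report_payload <- function(x) {
  if (inherits(x, "lyl_estimate")) {
    list(kind = "point", condition_age = x$condition_age, tau = x$tau,
         n_at_risk = x$n_at_risk, life_exp = x$life_exp,
         lyl_total = x$lyl_total, lyl_by_cause = as.list(x$lyl_by_cause))
  } else if (inherits(x, "lyl_summary")) {
    list(kind = "weighted_summary", tau = x$tau, age_range = x$age_range,
         n_cases = x$n_cases, life_exp = x$life_exp,
         lyl_total = x$lyl_total, lyl_by_cause = as.list(x$lyl_by_cause))
  } else if (inherits(x, "lyl_boot")) {
    base <- if (x$kind == "range") {
      list(kind = "range_bootstrap",
           table = report_table(x$point))
    } else {
      inner <- report_payload(x$point)
      inner$ci <- apply(x$ci, 2L, as.list)
      inner
    }
    c(base, list(level = x$level, niter = x$niter, seed = x$seed))
  } else if (inherits(x, "lyl_table")) {
    list(kind = "range", tau = attr(x, "tau"), table = report_table(x))
  } else if (inherits(x, "lyl_excess")) {
    out <- list(kind = "excess", lyl_diff = as.list(x$lyl_diff),
                le_diff = x$le_diff)
    if (!is.null(x$ci)) {
      out$ci <- apply(x$ci, 2L, as.list)
      out$level <- x$level
    }
    out
  } else if (inherits(x, "lyl_excess_ref")) {
    out <- list(kind = "excess_vs_lifetable", excess = x$excess,
                diseased_lyl = x$diseased_lyl,
                reference_lyl = x$reference_lyl,
                diseased_by_cause = as.list(x$diseased_by_cause),
                tau = x$tau)
    if (!is.null(x$ci)) {
      out$ci <- as.list(x$ci)
      out$level <- x$level
    }
    out
  } else if (inherits(x, "lyl_agg_estimate")) {
    list(kind = "aggregated", condition_age = x$condition_age, tau = x$tau,
         diseased_lyl = x$diseased_lyl, reference_lyl = x$reference_lyl,
         excess = x$excess)
  } else if (inherits(x, "lyl_agg_summary")) {
    list(kind = "aggregated_range", age_range = x$age_range, tau = x$tau,
         n_cases = x$n_cases, diseased_lyl = x$diseased_lyl,
         reference_lyl = x$reference_lyl, excess = x$excess)
  } else {
    stop("cannot serialize object of class ", paste(class(x), collapse = "/"))
  }
}

report_table <- function(x) {
  if (inherits(x, "lyl_boot")) x <- x$point
  if (inherits(x, "lyl_table")) return(as.data.frame(x))
  if (inherits(x, "lyl_agg_summary")) return(x$table)
  NULL
}

#' Per-age comparison table for two range results
#'
#' Joins the per-age tables of a diseased and a reference range run into a
#' single layout: cases, life expectancy, life lost and per-cause life lost
#' for both groups, plus their differences (diseased minus reference).
#'
#' @param diseased,reference `lyl_table` objects on the same ages and tau.
#' @param weights optional [weights_from_onsets()] supplying the per-age
#'   case counts (defaults to the diseased table's risk-set sizes being
#'   omitted; cases are then NA).
#' @return A data.frame, one row per age.
#' @export
excess_lyl_table <- function(diseased, reference, weights = NULL) {
  if (!identical(diseased$age, reference$age)) {
    stop("age grids differ between the two tables")
  }
  if (!isTRUE(all.equal(attr(diseased, "tau"), attr(reference, "tau")))) {
    stop("tau differs between the two tables")
  }
  causes <- attr(diseased, "cause_labels")
  out <- data.frame(age = diseased$age)
  out$cases <- if (is.null(weights)) NA_real_ else {
    as.numeric(weights)[match(out$age, as.integer(names(weights)))]
  }
  out$life_exp_diseased <- diseased$life_exp
  out$lyl_diseased <- diseased$lyl_total
  for (k in causes) out[[paste0("lyl_", k, "_diseased")]] <-
    diseased[[paste0("lyl_", k)]]
  out$life_exp_reference <- reference$life_exp
  out$lyl_reference <- reference$lyl_total
  ref_causes <- attr(reference, "cause_labels")
  for (k in ref_causes) out[[paste0("lyl_", k, "_reference")]] <-
    reference[[paste0("lyl_", k)]]
  out$lyl_diff <- diseased$lyl_total - reference$lyl_total
  if (identical(causes, ref_causes)) {
    for (k in causes) {
      out[[paste0("lyl_", k, "_diff")]] <-
        diseased[[paste0("lyl_", k)]] - reference[[paste0("lyl_", k)]]
    }
  }
  out
}
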