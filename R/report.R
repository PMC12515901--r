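#' Render a half-open month interval as a report age label
#'
#' Report tables label each bin the way pediatric reference-interval
#' tables do: sub-year or non-year-aligned boundaries in months
#' ("3 mths"), year-aligned boundaries in whole years ("1 yrs"), the
#' upper bound shown as the last included month/year, and an open-ended
#' top bin as "N yrs-" (en dash). The rendering is lossless:
#' [parse_age_label()] recovers the exact month interval.
#'
#' @param lo_months,hi_months Half-open interval `[lo, hi)` in months;
#'   `hi_months = Inf` renders an open-ended bin.
#' @return Character label.
#' @examples
#' format_age_label(3, 12)    # "3 mths–11 mths"
#' format_age_label(12, 108)  # "1 yrs–8 yrs"
#' format_age_label(120, Inf) # "10 yrs–"
#' @export
format_age_label <- function(lo_months, hi_months) {
  stopifnot(lo_months >= 0, lo_months < hi_months)
  fmt_start <- function(m) {
    if (m >= 12 && m %% 12 == 0) sprintf("%d yrs", m %/% 12)
    else sprintf("%d mths", m)
  }
  if (is.infinite(hi_months)) return(paste0(fmt_start(lo_months), "–"))
  e <- hi_months - 1
  end <- if (hi_months %% 12 == 0 && e >= 12) sprintf("%d yrs", e %/% 12)
    else sprintf("%d mths", e)
  paste0(fmt_start(lo_months), "–", end)
}

#' @rdname format_age_label
#' @param label A label produced by [format_age_label()].
#' @return `parse_age_label()`: numeric `c(lo, hi)` in months.
#' @export
parse_age_label <- function(label) {
  parts <- strsplit(label, "–")[[1]]
  to_months <- function(s) {
    m <- regmatches(s, regexec("^(\\d+) (mths|yrs)$", s))[[1]]
    if (length(m) != 3L) stop("parse_age_label: cannot parse '", s, "'")
    as.numeric(m[2]) * if (m[3] == "yrs") 12 else 1
  }
  lo <- to_months(parts[1])
  if (length(parts) == 1L || !nzchar(parts[2])) return(c(lo, Inf))
  s <- parts[2]
  m <- regmatches(s, regexec("^(\\d+) (mths|yrs)$", s))[[1]]
  hi <- if (m[3] == "yrs") (as.numeric(m[2]) + 1) * 12
    else as.numeric(m[2]) + 1
  c(lo, hi)
}

#' Run the full indirect reference-interval pipeline
#'
#' Per analyte and sex: iterated Tukey cleaning within whole-year cells,
#' age-tree candidate cuts, Harris-Boyd/Lahti-validated partition
#' refinement, then a per-bin inverse Box-Cox fit with percentile-
#' bootstrap confidence intervals. Sex is always a hard partition; age
#' partitions are per analyte and sex. An analyte-sex stratum with fewer
#' than `2 * min_leaf` records is estimated as a single bin and flagged.
#' A bin whose bootstrap aborts (over 10% replicate failures, typical
#' only of very small bins) keeps its point estimates and reports `NA`
#' CIs under a `ci-failed` flag, so the report always carries exactly
#' one row per final bin. The top age bin of every partition is
#' reported open-ended. The whole run is deterministic given `seed`.
#'
#' @param records Measurement table: columns `analyte`, `sex`,
#'   `age_months`, `value` (a `truth_flag` column, if present, is
#'   ignored: the pipeline never peeks).
#' @param min_leaf Minimum records per partition bin (default 50).
#' @param max_depth Tree depth for candidate cuts (default 2).
#' @param B Bootstrap replicates per bin (default 200).
#' @param seed Integer seed driving all bootstrap resampling.
#' @param ... Passed to [fit_indirect_model()] (e.g. `lambda_grid`).
#' @return List of class `"pedri_report"`:
#' \describe{
#'   \item{report}{data frame, one row per final bin: `analyte`, `sex`,
#'     `age_label`, `age_lo`, `age_hi`, `n`, point limits `median`,
#'     `lower`, `upper`, their CI bounds (`*_ci_lo`, `*_ci_hi`),
#'     `lambda`, `flags`.}
#'   \item{partitions}{named list of `"pedri_partition"` audits.}
#'   \item{removed}{records dropped by cleaning.}
#' }
#' @export
run_pipeline <- function(records, min_leaf = 50L, max_depth = 2L,
                         B = 200L, seed = 1L, ...) {
  need <- c("analyte", "sex", "age_months", "value")
  stopifnot(all(need %in% names(records)))
  cleaned <- clean_cohort(records)
  kept <- cleaned$kept
  strata <- unique(kept[, c("analyte", "sex")])
  strata <- strata[order(strata$analyte, strata$sex), , drop = FALSE]
  set.seed(as.integer(seed))
  task_seed <- sample.int(.Machine$integer.max,
                          nrow(strata) * 64L)  # ample per-bin seeds
  rows <- list()
  partitions <- list()
  tk <- 0L
  for (r in seq_len(nrow(strata))) {
    an <- strata$analyte[r]; sx <- strata$sex[r]
    sub <- kept[kept$analyte == an & kept$sex == sx, , drop = FALSE]
    fallback <- nrow(sub) < 2L * min_leaf
    part <- if (fallback) {
      lo <- min(sub$age_months); hi <- max(sub$age_months) + 1L
      structure(list(analyte = an, sex = sx, edges = c(lo, hi),
                     bins = data.frame(age_lo = lo, age_hi = hi,
                                       n = nrow(sub)),
                     decisions = NULL, passes = 0L),
                class = "pedri_partition")
    } else {
      cuts <- fit_age_tree(sub$age_months, sub$value,
                           max_depth = max_depth, min_leaf = min_leaf)
      refine_partition(sub, cuts, min_leaf = min_leaf,
                       max_depth = max_depth, analyte = an, sex = sx)
    }
    partitions[[paste(an, sx, sep = ".")]] <- part
    nb <- nrow(part$bins)
    for (b in seq_len(nb)) {
      v <- sub$value[sub$age_months >= part$bins$age_lo[b] &
                     sub$age_months < part$bins$age_hi[b]]
      tk <- tk + 1L
      ci_failed <- FALSE
      ri <- tryCatch(
        suppressWarnings(bootstrap_ci(v, B = B, seed = task_seed[tk], ...)),
        error = function(e) NULL)
      if (is.null(ri)) {
        # bootstrap too fragile for this bin (e.g. tiny n): keep the
        # point estimates, mark the CIs unavailable
        ci_failed <- TRUE
        fit <- suppressWarnings(fit_indirect_model(v, ...))
        pt <- reference_interval(fit)
        ri <- list(lower = unname(pt["lower"]), median = unname(pt["median"]),
                   upper = unname(pt["upper"]),
                   ci_lower = c(NA_real_, NA_real_),
                   ci_median = c(NA_real_, NA_real_),
                   ci_upper = c(NA_real_, NA_real_),
                   lambda = fit$lambda)
      }
      flags <- c(if (length(v) < 120L) "n<120",
                 if (fallback) "single-bin-fallback",
                 if (ci_failed) "ci-failed")
      hi_lab <- if (b == nb) Inf else part$bins$age_hi[b]
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = an, sex = sx,
        age_label = format_age_label(part$bins$age_lo[b], hi_lab),
        age_lo = part$bins$age_lo[b], age_hi = hi_lab,
        n = length(v),
        median = ri$median, median_ci_lo = ri$ci_median[1],
        median_ci_hi = ri$ci_median[2],
        lower = ri$lower, lower_ci_lo = ri$ci_lower[1],
        lower_ci_hi = ri$ci_lower[2],
        upper = ri$upper, upper_ci_lo = ri$ci_upper[1],
        upper_ci_hi = ri$ci_upper[2],
        lambda = ri$lambda,
        flags = paste(flags, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report, partitions = partitions,
                 removed = cleaned$removed),
            class = "pedri_report")
}

#' Format a report as a human-readable table
#'
#' Values rounded to two decimals in the printed table (full precision
#' is retained in the underlying data frame), one line per bin with
#' `estimate (ci_lo, ci_hi)` columns for median, lower and upper limit.
#'
#' @param x A `"pedri_report"`.
#' @param ... Unused.
#' @export
print.pedri_report <- function(x, ...) {
  r <- x$report
  fmt <- function(est, lo, hi) sprintf("%.2f (%.2f, %.2f)", est, lo, hi)
  out <- data.frame(
    Analyte = r$analyte, Sex = r$sex, Age = r$age_label, n = r$n,
    Median = fmt(r$median, r$median_ci_lo, r$median_ci_hi),
    Lower = fmt(r$lower, r$lower_ci_lo, r$lower_ci_hi),
    Upper = fmt(r$upper, r$upper_ci_lo, r$upper_ci_hi),
    Flags = r$flags)
  print(out, row.names = FALSE, right = FALSE)
  invisible(x)
}
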