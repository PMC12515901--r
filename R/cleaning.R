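#' Linear-interpolation quantile
#'
#' Single quantile convention shared by every module (Tukey fences, Lahti
#' limits, subgroup summaries, the inverse estimator): sort the values
#' ascending, set `h = (n - 1) * p + 1`, and linearly interpolate between
#' the order statistics bracketing `h`. This is the classic
#' mode-7 convention; `p = 0` returns the minimum and `p = 1` the maximum.
#'
#' @param values Non-empty numeric vector.
#' @param p Probability (vectorised), each in \[0, 1\].
#' @return Numeric vector of quantiles, one per element of `p`.
#' @examples
#' compute_quantile(c(1, 2, 3, 4), 0.25) # 1.75
#' @export
compute_quantile <- function(values, p) {
  if (length(values) == 0L) stop("compute_quantile: empty input")
  stopifnot(is.numeric(values), all(is.finite(values)),
            is.numeric(p), all(p >= 0), all(p <= 1))
  x <- sort(values)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- pmin(floor(h), n)
  frac <- h - lo
  x[lo] + frac * (x[pmin(lo + 1L, n)] - x[lo])
}

#' Tukey fences for outlier flagging
#'
#' Fences at `Q1 - k * IQR` and `Q3 + k * IQR` with the conventional
#' multiplier `k = 1.5`. Values strictly outside the fences are treated as
#' outliers by [iterative_tukey_clean()]; boundary values are kept.
#' Below `n = 8` observations the quartiles are too unstable to anchor
#' fences, so the function signals a condition of class
#' `"pedri_too_small"` and callers keep all values.
#'
#' @param values Numeric vector, `length(values) >= 8`.
#' @param k Fence multiplier (default 1.5).
#' @return Named numeric vector `c(lower = , upper = )`.
#' @export
tukey_fences <- function(values, k = 1.5) {
  if (length(values) < 8L) {
    stop(structure(
      class = c("pedri_too_small", "error", "condition"),
      list(message = sprintf(
        "tukey_fences: n = %d is too small to clean (need >= 8)",
        length(values)), call = sys.call(-1))))
  }
  q <- compute_quantile(values, c(0.25, 0.75))
  iqr <- q[2] - q[1]
  c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
}

#' Iterated Tukey outlier removal
#'
#' Repeatedly computes Tukey fences on the currently kept values and drops
#' values strictly outside them, until a pass removes nothing. The loop
#' always terminates: each removing pass strictly shrinks the kept set,
#' and the fences always contain the quartiles, so the kept set can never
#' empty out. Inputs with fewer than 8 values are returned unchanged
#' (with a warning) because fences are not computed below that size.
#'
#' @param values Numeric vector, `length(values) >= 1`.
#' @param k Fence multiplier passed to [tukey_fences()].
#' @return A list of class `"pedri_clean"`:
#' \describe{
#'   \item{kept}{values surviving all passes (a fixed point: one further
#'     pass removes nothing).}
#'   \item{removed}{data frame with columns `value` and `iteration`
#'     (1-based pass in which each value was dropped).}
#'   \item{n_iterations}{number of fence passes performed (>= 1).}
#'   \item{fences}{data frame of `lower`/`upper` fence per pass.}
#' }
#' @examples
#' res <- iterative_tukey_clean(c(rnorm(50), 25))
#' res$n_iterations
#' @export
iterative_tukey_clean <- function(values, k = 1.5) {
  stopifnot(length(values) >= 1L, is.numeric(values), all(is.finite(values)))
  kept <- values
  removed_val <- numeric(0)
  removed_it <- integer(0)
  fences <- list()
  it <- 0L
  if (length(kept) < 8L) {
    warning(sprintf("n = %d < 8: cell passed through uncleaned",
                    length(kept)))
    return(structure(list(kept = kept,
                          removed = data.frame(value = numeric(0),
                                               iteration = integer(0)),
                          n_iterations = 1L,
                          fences = data.frame(lower = numeric(0),
                                              upper = numeric(0))),
                     class = "pedri_clean"))
  }
  repeat {
    it <- it + 1L
    f <- tukey_fences(kept, k)
    fences[[it]] <- f
    out <- kept < f[["lower"]] | kept > f[["upper"]]
    if (!any(out)) break
    removed_val <- c(removed_val, kept[out])
    removed_it <- c(removed_it, rep.int(it, sum(out)))
    kept <- kept[!out]
    stopifnot(length(kept) > 0L) # fences contain Q1..Q3
    if (length(kept) < 8L) break # next pass impossible; stop here
  }
  fdf <- as.data.frame(do.call(rbind, fences))
  names(fdf) <- c("lower", "upper")
  structure(list(kept = kept,
                 removed = data.frame(value = removed_val,
                                      iteration = removed_it),
                 n_iterations = it,
                 fences = fdf),
            class = "pedri_clean")
}

#' Clean a measurement table per analyte x sex x whole-year age cell
#'
#' Applies [iterative_tukey_clean()] within each analyte-by-sex-by-year
#' cell, the subgrouping resolution at which the downstream partitioning
#' analysis operates. Cleaning happens once, up front, before any age
#' bins are merged. Cells with fewer than 8 observations are kept intact.
#'
#' @param records Data frame with at least columns `analyte`, `sex`,
#'   `age_months`, `value`.
#' @param k Fence multiplier.
#' @return A list with `kept` (the cleaned records, same columns) and
#'   `removed` (dropped records plus columns `iteration` and `cell`).
#' @export
clean_cohort <- function(records, k = 1.5) {
  need <- c("analyte", "sex", "age_months", "value")
  stopifnot(all(need %in% names(records)))
  year <- records$age_months %/% 12L
  cell <- interaction(records$analyte, records$sex, year, drop = TRUE)
  keep_idx <- logical(nrow(records))
  rem_rows <- list()
  for (cl in levels(cell)) {
    idx <- which(cell == cl)
    res <- withCallingHandlers(
      iterative_tukey_clean(records$value[idx], k),
      warning = function(w) invokeRestart("muffleWarning"))
    if (nrow(res$removed) == 0L) {
      keep_idx[idx] <- TRUE
      next
    }
    # map removed values back to row indices (multiset-safe)
    drop_local <- integer(0)
    pool <- res$removed$value
    vals <- records$value[idx]
    for (j in seq_along(pool)) {
      hit <- which(vals == pool[j] & !(seq_along(idx) %in% drop_local))[1]
      drop_local <- c(drop_local, hit)
    }
    keep_idx[idx[-drop_local]] <- TRUE
    rr <- records[idx[drop_local], , drop = FALSE]
    rr$iteration <- res$removed$iteration
    rr$cell <- cl
    rem_rows[[cl]] <- rr
  }
  removed <- if (length(rem_rows)) do.call(rbind, rem_rows) else
    cbind(records[0, , drop = FALSE],
          data.frame(iteration = integer(0), cell = character(0)))
  rownames(removed) <- NULL
  list(kept = records[keep_idx, , drop = FALSE], removed = removed)
}
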