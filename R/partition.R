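#' Summaries per half-open age bin
#'
#' Computes n, mean, SD (n-1 denominator) and the 2.5th/50th/97.5th
#' quantiles of the values falling in each half-open month bin. These
#' summaries are the currency of the Harris-Boyd comparison of adjacent
#' subgroups. Empty bins are omitted with a warning; a single-observation
#' bin reports SD 0.
#'
#' @param records Data frame with columns `age_months` and `value`
#'   (single analyte and sex).
#' @param edges Increasing numeric vector of bin edges in months; bin `i`
#'   is `[edges[i], edges[i+1])`.
#' @return Data frame with one row per non-empty bin: `age_lo`, `age_hi`,
#'   `n`, `mean`, `sd`, `q025`, `q500`, `q975`.
#' @export
subgroup_summaries <- function(records, edges) {
  stopifnot(all(c("age_months", "value") %in% names(records)),
            length(edges) >= 2L, all(diff(edges) > 0))
  rows <- list()
  for (i in seq_len(length(edges) - 1L)) {
    v <- records$value[records$age_months >= edges[i] &
                       records$age_months < edges[i + 1L]]
    if (!length(v)) {
      warning(sprintf("empty bin [%s, %s) omitted", edges[i], edges[i + 1L]))
      next
    }
    q <- compute_quantile(v, c(0.025, 0.5, 0.975))
    rows[[length(rows) + 1L]] <- data.frame(
      age_lo = edges[i], age_hi = edges[i + 1L], n = length(v),
      mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
      q025 = q[1], q500 = q[2], q975 = q[3])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# best single SSE-reducing split of (ages, values); NULL when no split
# achieves positive gain (beyond 1e-12 relative) with both children of
# size >= min_leaf. Ties in gain go to the youngest threshold.
best_split <- function(ages, values, min_leaf) {
  n <- length(ages)
  if (n < 2L * min_leaf) return(NULL)
  o <- order(ages)
  a <- ages[o]; y <- values[o]
  # candidate boundaries: after the last observation of each distinct age
  last <- which(diff(a) > 0)          # split after position `last`
  if (!length(last)) return(NULL)
  cs <- cumsum(y); css <- cumsum(y^2)
  tot_s <- cs[n]; tot_ss <- css[n]
  sse_tot <- tot_ss - tot_s^2 / n
  m <- last
  ok <- m >= min_leaf & (n - m) >= min_leaf
  if (!any(ok)) return(NULL)
  m <- m[ok]
  sse_l <- css[m] - cs[m]^2 / m
  sse_r <- (tot_ss - css[m]) - (tot_s - cs[m])^2 / (n - m)
  gain <- sse_tot - (sse_l + sse_r)
  tol <- 1e-12 * max(sse_tot, 1e-300)
  if (max(gain) <= tol) return(NULL)
  best <- which(gain >= max(gain) - tol)[1]  # youngest among ties
  list(threshold = (a[m[best]] + a[m[best] + 1L]) / 2,
       gain = gain[best], pos = m[best])
}

#' Depth-limited regression-tree age cuts
#'
#' Recursive binary splitting on age alone, the CART proposal step for
#' candidate age partitions: each node splits at the midpoint between
#' consecutive distinct observed ages that maximises the reduction in
#' within-node sum of squared errors, subject to both children holding
#' at least `min_leaf` observations; recursion stops at `max_depth`.
#' A node whose best achievable gain is zero (within 1e-12 relative)
#' does not split; gain ties resolve to the youngest age.
#'
#' @param ages Integer ages in months.
#' @param values Paired measurement values.
#' @param max_depth Maximum tree depth (default 2, so at most 3 cuts).
#' @param min_leaf Minimum observations per leaf (default 50).
#' @return Sorted numeric vector of cut thresholds in months (possibly
#'   empty).
#' @export
fit_age_tree <- function(ages, values, max_depth = 2L, min_leaf = 50L) {
  stopifnot(length(ages) == length(values), max_depth >= 1L, min_leaf >= 1L)
  cuts <- numeric(0)
  recurse <- function(idx, depth) {
    if (depth > max_depth) return(invisible())
    sp <- best_split(ages[idx], values[idx], min_leaf)
    if (is.null(sp)) return(invisible())
    cuts <<- c(cuts, sp$threshold)
    recurse(idx[ages[idx] < sp$threshold], depth + 1L)
    recurse(idx[ages[idx] >= sp$threshold], depth + 1L)
  }
  recurse(seq_along(ages), 1L)
  sort(cuts)
}

#' Harris-Boyd comparison of two adjacent subgroups
#'
#' The z statistic for the difference of subgroup means,
#' `z = (mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2)`, is compared with
#' the sample-size-scaled critical value `z* = 3 * sqrt((n1 + n2)/240)`;
#' `|z| > z*` recommends keeping the subgroups separate. Independently,
#' a ratio of the larger to the smaller SD above 1.5 also recommends a
#' split, because a common interval would mis-cover the tighter group.
#'
#' @param s1,s2 Single rows of [subgroup_summaries()] output (or any list
#'   with `n`, `mean`, `sd`), each with `n >= 2`.
#' @return List of class `"pedri_hb"`: `z`, `z_star`, `sd_ratio`,
#'   `split_by_z`, `split_by_sd`.
#' @export
harris_boyd <- function(s1, s2) {
  n1 <- s1$n; n2 <- s2$n
  stopifnot(n1 >= 2L, n2 >= 2L)
  z_star <- 3 * sqrt((n1 + n2) / 240)
  se <- sqrt(s1$sd^2 / n1 + s2$sd^2 / n2)
  if (se == 0) {
    if (s1$mean == s2$mean) {
      z <- 0
    } else {
      warning("harris_boyd: zero variance with unequal means; z set to Inf")
      z <- Inf * sign(s1$mean - s2$mean)
    }
  } else {
    z <- (s1$mean - s2$mean) / se
  }
  sd_ratio <- if (s1$sd == 0 && s2$sd == 0) 1 else
    max(s1$sd, s2$sd) / min(s1$sd, s2$sd)
  structure(list(z = z, z_star = z_star, sd_ratio = sd_ratio,
                 split_by_z = abs(z) > z_star,
                 split_by_sd = sd_ratio > 1.5),
            class = "pedri_hb")
}

#' Lahti proportionality check of two adjacent subgroups
#'
#' Pools both subgroups, takes the pooled 2.5th and 97.5th percentiles
#' as common reference limits, and measures the percentage of each
#' subgroup strictly outside each limit. If any of the four percentages
#' reaches 4.1% or falls to 0.9% or below, the subgroups are too unlike
#' for a common interval and a split is advised.
#'
#' The percentages are observed counts, so their resolution is `100/n`:
#' below `n = 112` a percentage in `(0, 0.9]` cannot even be realised
#' and the low-proportion rule degenerates to "zero tail observations",
#' which homogeneous subgroups hit routinely by chance. The test is
#' therefore only offered to subgroups of at least `min_n = 120`
#' observations (also the conventional minimum reference-subgroup
#' size); smaller pairs signal a condition of class
#' `"pedri_lahti_insufficient"` and callers treat them as not
#' supporting a split.
#'
#' @param values1,values2 Numeric value vectors of the two subgroups.
#' @param min_n Minimum observations per subgroup (default 120).
#' @return List of class `"pedri_lahti"`: `common_lower`, `common_upper`,
#'   `proportions` (named percentages: `p1_below`, `p1_above`,
#'   `p2_below`, `p2_above`), `split`.
#' @export
lahti <- function(values1, values2, min_n = 120L) {
  if (length(values1) < min_n || length(values2) < min_n) {
    stop(structure(
      class = c("pedri_lahti_insufficient", "error", "condition"),
      list(message = sprintf(
        "lahti: subgroup sizes %d and %d insufficient (need >= %d)",
        length(values1), length(values2), min_n), call = sys.call(-1))))
  }
  combined <- c(values1, values2)
  lim <- compute_quantile(combined, c(0.025, 0.975))
  prop <- function(v) {
    100 * c(below = sum(v < lim[1]), above = sum(v > lim[2])) / length(v)
  }
  p <- c(prop(values1), prop(values2))
  names(p) <- c("p1_below", "p1_above", "p2_below", "p2_above")
  structure(list(common_lower = lim[1], common_upper = lim[2],
                 proportions = p,
                 split = any(p >= 4.1 | p <= 0.9)),
            class = "pedri_lahti")
}

# evaluate the three split criteria for the pair of bins around one cut;
# returns the audit fields plus the combined verdict
evaluate_pair <- function(v1, v2) {
  s1 <- list(n = length(v1), mean = mean(v1),
             sd = if (length(v1) > 1) stats::sd(v1) else 0)
  s2 <- list(n = length(v2), mean = mean(v2),
             sd = if (length(v2) > 1) stats::sd(v2) else 0)
  hb <- harris_boyd(s1, s2)
  lh <- tryCatch(lahti(v1, v2),
                 pedri_lahti_insufficient = function(e) NULL)
  lahti_split <- if (is.null(lh)) FALSE else lh$split
  props <- if (is.null(lh)) rep(NA_real_, 4) else unname(lh$proportions)
  list(n1 = s1$n, n2 = s2$n, z = hb$z, z_star = hb$z_star,
       sd_ratio = hb$sd_ratio, split_by_z = hb$split_by_z,
       split_by_sd = hb$split_by_sd, lahti_split = lahti_split,
       p1_below = props[1], p1_above = props[2],
       p2_below = props[3], p2_above = props[4],
       any_split = hb$split_by_z || hb$split_by_sd || lahti_split)
}

#' Refine candidate age cuts into a validated partition
#'
#' Starts from the bins induced by the candidate cuts (plus the data's
#' age-span endpoints) and alternates two phases until stable: a merge
#' phase that scans adjacent bin pairs left to right and merges a pair
#' whenever none of the three criteria (Harris-Boyd z test, SD-ratio
#' rule, Lahti proportionality) supports keeping them separate; then a
#' re-subdivision phase that re-runs the age tree inside each bin and
#' accepts a proposed cut only if the same three criteria validate it.
#' A cut month that a merge decision has removed is never re-proposed:
#' the pair a cut is tested against changes as its neighbours merge, so
#' re-admitting removed cuts can cycle indefinitely between
#' configurations; blocking them guarantees termination and resolves
#' oscillating cuts in favour of merging, the conservative direction.
#' Every decision is appended to an audit table. The loop is capped at
#' 20 passes. No accepted cut ever creates a bin with fewer than
#' `min_leaf` observations.
#'
#' @param records Data frame with `age_months` and `value` (one analyte
#'   and sex, already cleaned).
#' @param candidate_cuts Numeric cut thresholds in months (e.g. from
#'   [fit_age_tree()]); non-integer thresholds are rounded up to the
#'   first month of the right-hand bin.
#' @param min_leaf Minimum observations per final bin (default 50).
#' @param max_depth Tree depth used during re-subdivision (default 2).
#' @param analyte,sex Optional labels carried into the result.
#' @return List of class `"pedri_partition"`: `analyte`, `sex`, `edges`
#'   (integer month edges, half-open bins), `bins` (data frame `age_lo`,
#'   `age_hi`, `n`), `decisions` (audit data frame), `passes`.
#' @export
refine_partition <- function(records, candidate_cuts, min_leaf = 50L,
                             max_depth = 2L, analyte = NA_character_,
                             sex = NA_character_) {
  stopifnot(all(c("age_months", "value") %in% names(records)),
            nrow(records) >= 1L)
  ages <- records$age_months
  values <- records$value
  lo <- min(ages); hi <- max(ages) + 1L
  cuts <- sort(unique(ceiling(candidate_cuts)))
  cuts <- cuts[cuts > lo & cuts < hi]
  edges <- c(lo, cuts, hi)
  audit <- list()
  note <- function(pass, phase, cut_at, ev, action) {
    audit[[length(audit) + 1L]] <<- data.frame(
      pass = pass, phase = phase, cut_month = cut_at,
      n1 = ev$n1, n2 = ev$n2, z = ev$z, z_star = ev$z_star,
      sd_ratio = ev$sd_ratio, split_by_z = ev$split_by_z,
      split_by_sd = ev$split_by_sd, lahti_split = ev$lahti_split,
      p1_below = ev$p1_below, p1_above = ev$p1_above,
      p2_below = ev$p2_below, p2_above = ev$p2_above,
      action = action)
  }
  bin_values <- function(l, h) values[ages >= l & ages < h]

  # drop initial cuts that leave a bin under min_leaf: merge each
  # undersized bin into its smaller neighbour (left on ties)
  repeat {
    nb <- vapply(seq_len(length(edges) - 1L), function(i)
      sum(ages >= edges[i] & ages < edges[i + 1L]), 0L)
    small <- which(nb < min_leaf)
    if (!length(small) || length(edges) == 2L) break
    i <- small[1]
    drop_cut <- if (i == 1L) 2L
      else if (i == length(nb)) length(edges) - 1L
      else if (nb[i - 1L] <= nb[i + 1L]) i else i + 1L
    edges <- edges[-drop_cut]
  }

  pass <- 0L
  blocked <- numeric(0)  # cut months removed by a merge decision
  repeat {
    pass <- pass + 1L
    changed <- FALSE
    # merge phase: greedy left-to-right
    i <- 1L
    while (i <= length(edges) - 2L) {
      v1 <- bin_values(edges[i], edges[i + 1L])
      v2 <- bin_values(edges[i + 1L], edges[i + 2L])
      ev <- evaluate_pair(v1, v2)
      if (!ev$any_split) {
        note(pass, "merge", edges[i + 1L], ev, "merge")
        blocked <- c(blocked, edges[i + 1L])
        edges <- edges[-(i + 1L)]
        changed <- TRUE
      } else {
        note(pass, "merge", edges[i + 1L], ev, "keep")
        i <- i + 1L
      }
    }
    # re-subdivision phase: only once merging is stable this pass
    if (!changed) {
      for (i in seq_len(length(edges) - 1L)) {
        in_bin <- ages >= edges[i] & ages < edges[i + 1L]
        prop <- fit_age_tree(ages[in_bin], values[in_bin],
                             max_depth = max_depth, min_leaf = min_leaf)
        for (cut in sort(unique(ceiling(prop)))) {
          if (cut <= edges[i] || cut >= edges[i + 1L]) next
          if (cut %in% blocked) next
          v1 <- values[in_bin & ages < cut]
          v2 <- values[in_bin & ages >= cut]
          if (length(v1) < min_leaf || length(v2) < min_leaf) next
          ev <- evaluate_pair(v1, v2)
          if (ev$any_split) {
            note(pass, "subdivide", cut, ev, "add")
            edges <- sort(c(edges, cut))
            changed <- TRUE
            break  # bin boundaries moved; revalidate next pass
          } else {
            note(pass, "subdivide", cut, ev, "reject")
          }
        }
        if (changed) break
      }
    }
    if (!changed || pass >= 20L) break
  }

  bins <- data.frame(
    age_lo = edges[-length(edges)], age_hi = edges[-1],
    n = vapply(seq_len(length(edges) - 1L), function(i)
      sum(ages >= edges[i] & ages < edges[i + 1L]), 0L))
  decisions <- if (length(audit)) do.call(rbind, audit) else
    data.frame(pass = integer(0), phase = character(0),
               cut_month = numeric(0), n1 = integer(0), n2 = integer(0),
               z = numeric(0), z_star = numeric(0), sd_ratio = numeric(0),
               split_by_z = logical(0), split_by_sd = logical(0),
               lahti_split = logical(0), p1_below = numeric(0),
               p1_above = numeric(0), p2_below = numeric(0),
               p2_above = numeric(0), action = character(0))
  structure(list(analyte = analyte, sex = sex, edges = edges,
                 bins = bins, decisions = decisions, passes = pass),
            class = "pedri_partition")
}
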