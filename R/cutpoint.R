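# Best-P-value cutpoint search against survival (X-tile emulation).
#
# The two-group log-rank statistic is evaluated at every admissible
# split of the sorted marker via cumulative-sum tables, so the
# exhaustive scan is O(n * d) overall (d = distinct event times).

# Precompute, for patients sorted by marker: cumulative at-risk and
# event counts per distinct event time, plus totals.
logrank_tables <- function(marker, time, event) {
  stopifnot(length(marker) == length(time), length(time) == length(event),
            all(time >= 0), all(event %in% c(0, 1)))
  ord <- order(marker, time)
  time <- time[ord]; event <- event[ord]; marker <- marker[ord]
  ut <- sort(unique(time[event == 1]))
  if (!length(ut)) stop("cutpoint search: no events", call. = FALSE)
  Y <- outer(time, ut, ">=") * 1          # n x d at-risk indicators
  D <- outer(time, ut, "==") * event      # n x d event indicators
  list(marker = marker, n = length(time),
       ut = ut,
       CY = apply(Y, 2, cumsum), CD = apply(D, 2, cumsum),
       nj = colSums(Y), dj = colSums(D))
}

# chi2 of the two-group log-rank test for group 1 = sorted patients
# 1..a, for each candidate index a (vectorized).
logrank_chi2_splits <- function(tab, idx) {
  n1 <- tab$CY[idx, , drop = FALSE]       # |idx| x d at-risk in group 1
  d1 <- tab$CD[idx, , drop = FALSE]
  nj <- tab$nj; dj <- tab$dj
  O <- rowSums(d1)
  E <- as.numeric(n1 %*% (dj / nj))
  vj_scale <- dj * ifelse(nj > 1, (nj - dj) / (nj - 1), 0)
  p1 <- sweep(n1, 2, nj, "/")
  V <- as.numeric((p1 * (1 - p1)) %*% vj_scale)
  chi2 <- ifelse(V > 0, (O - E)^2 / V, 0)
  chi2
}

#' Optimal survival cutpoint by the best-P-value principle
#'
#' Emulates the X-tile search: the two-group log-rank statistic is
#' evaluated at every admissible split of the observed marker values
#' (candidate cutoffs are midpoints between consecutive distinct
#' values; both groups must contain at least `min_group_frac` of the
#' cohort) and the cutoff maximizing the statistic is returned. Because
#' the maximum of many correlated tests is anti-conservative, the
#' Miller-Siegmund corrected P-value for maximally selected rank
#' statistics is reported alongside the raw one.
#'
#' @param marker Continuous marker (e.g. TSR fraction or total points).
#' @param time Follow-up in months.
#' @param event Event indicator (0/1).
#' @param min_group_frac Minimum fraction of patients on each side of
#'   the split (default 0.10).
#' @return Object of class `cutpoint_result`: `cutoff`, `chi2`, `p_raw`,
#'   `p_adjusted` (Miller-Siegmund), `group_sizes` (low = marker <=
#'   cutoff first), and the searched `candidates` table.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 120, seed = 5))
#' optimal_cutpoint(coh$tsr, coh$time_months, coh$event)
#' @export
optimal_cutpoint <- function(marker, time, event, min_group_frac = 0.10) {
  n <- length(marker)
  if (n < 20) stop("optimal_cutpoint: need at least 20 patients", call. = FALSE)
  if (sum(event) < 1) stop("optimal_cutpoint: need at least one event",
                           call. = FALSE)
  if (length(unique(marker)) < 2)
    stop("optimal_cutpoint: need at least 2 distinct marker values",
         call. = FALSE)
  tab <- logrank_tables(marker, time, event)
  m <- tab$marker
  lo <- ceiling(min_group_frac * n)
  hi <- n - lo
  idx <- which(seq_len(n - 1) >= lo & seq_len(n - 1) <= hi &
                 m[-n] < m[-1])
  if (!length(idx))
    stop("optimal_cutpoint: no admissible split under min_group_frac",
         call. = FALSE)
  chi2 <- logrank_chi2_splits(tab, idx)
  best <- idx[which.max(chi2)]            # ties: smallest cutoff wins
  chi2max <- max(chi2)
  cutoff <- (m[best] + m[best + 1]) / 2
  p_raw <- pchisq(chi2max, df = 1, lower.tail = FALSE)
  p_adj <- miller_siegmund_p(chi2max, min_group_frac, 1 - min_group_frac)
  structure(list(cutoff = cutoff, chi2 = chi2max, p_raw = p_raw,
                 p_adjusted = max(p_raw, min(1, p_adj)),
                 group_sizes = c(low = best, high = n - best),
                 candidates = data.frame(
                   cutoff = (m[idx] + m[idx + 1]) / 2, chi2 = chi2)),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(paste0("<cutpoint_result> cutoff = %.4g, chi2 = %.3f, ",
                     "p_raw = %.4g, p_adjusted = %.4g, groups %d/%d\n"),
              x$cutoff, x$chi2, x$p_raw, x$p_adjusted,
              x$group_sizes[1], x$group_sizes[2]))
  invisible(x)
}

# Miller-Siegmund improved Bonferroni bound for the maximally selected
# log-rank/chi-square statistic searched over the quantile band
# (eps1, eps2).
miller_siegmund_p <- function(chi2max, eps1, eps2) {
  b <- sqrt(chi2max)
  if (b < 1e-8) return(1)
  p <- dnorm(b) * (b - 1 / b) *
    log(((1 - eps1) * eps2) / (eps1 * (1 - eps2))) +
    4 * dnorm(b) / b
  min(1, max(p, 0))
}

#' Dichotomize a marker at a cutoff
#'
#' The boundary goes to the low group (`marker <= cutoff` is
#' stroma-low, `> cutoff` stroma-high).
#'
#' @param marker Numeric marker value(s).
#' @param cutoff Scalar cutoff.
#' @param labels Two labels (low, high).
#' @return Factor with the two labels.
#' @examples
#' categorize(c(0.555, 0.556), 0.555)
#' @export
categorize <- function(marker, cutoff,
                       labels = c("stroma-low", "stroma-high")) {
  factor(ifelse(marker <= cutoff, labels[1], labels[2]), levels = labels)
}

# 3-group log-rank chi2 (2 df) for groups (1..a), (a+1..b), (b+1..n) in
# marker order, from the precomputed cumulative tables.
logrank_chi2_pair <- function(tab, a, b) {
  nj <- tab$nj; dj <- tab$dj
  n1 <- tab$CY[a, ]; n2 <- tab$CY[b, ] - n1
  d1 <- tab$CD[a, ]; d2 <- tab$CD[b, ] - d1
  p1 <- n1 / nj; p2 <- n2 / nj
  O <- c(sum(d1), sum(d2))
  E <- c(sum(dj * p1), sum(dj * p2))
  s <- dj * ifelse(nj > 1, (nj - dj) / (nj - 1), 0)
  V11 <- sum(s * p1 * (1 - p1))
  V22 <- sum(s * p2 * (1 - p2))
  V12 <- -sum(s * p1 * p2)
  det <- V11 * V22 - V12^2
  u <- O - E
  if (abs(det) < 1e-12) {
    if (max(abs(u)) < 1e-8) return(0)
    return(NA_real_)
  }
  (u[1]^2 * V22 - 2 * u[1] * u[2] * V12 + u[2]^2 * V11) / det
}

#' Optimal pair of cutpoints for three risk groups
#'
#' Grid search over all admissible ordered pairs of splits (each of the
#' three groups at least `min_group_frac` of the cohort); the objective
#' is the overall 3-group log-rank chi-square. Ties are broken toward
#' the lexicographically smallest pair.
#'
#' @inheritParams optimal_cutpoint
#' @return List of class `two_cutpoint_result`: `cutoffs` (ordered
#'   pair), `chi2`, `p_raw` (2 df), `group_sizes`.
#' @export
optimal_two_cutpoints <- function(marker, time, event,
                                  min_group_frac = 0.10) {
  n <- length(marker)
  if (n < 30) stop("optimal_two_cutpoints: need at least 30 patients",
                   call. = FALSE)
  if (sum(event) < 1) stop("optimal_two_cutpoints: need at least one event",
                           call. = FALSE)
  tab <- logrank_tables(marker, time, event)
  m <- tab$marker
  gmin <- ceiling(min_group_frac * n)
  splits <- which(m[-n] < m[-1])          # split after index a
  ok_a <- splits[splits >= gmin]
  best <- NULL; best_chi2 <- -Inf
  for (a in ok_a) {
    bs <- splits[splits >= a + gmin & splits <= n - gmin]
    for (b in bs) {
      chi2 <- logrank_chi2_pair(tab, a, b)
      if (is.na(chi2)) chi2 <- 0
      if (chi2 > best_chi2 + 1e-12) {
        best_chi2 <- chi2
        best <- c(a, b)
      }
    }
  }
  if (is.null(best))
    stop("optimal_two_cutpoints: no admissible pair under min_group_frac",
         call. = FALSE)
  cutoffs <- c((m[best[1]] + m[best[1] + 1]) / 2,
               (m[best[2]] + m[best[2] + 1]) / 2)
  structure(list(cutoffs = cutoffs, chi2 = best_chi2,
                 p_raw = pchisq(best_chi2, df = 2, lower.tail = FALSE),
                 group_sizes = c(best[1], best[2] - best[1], n - best[2])),
            class = "two_cutpoint_result")
}

#' @export
print.two_cutpoint_result <- function(x, ...) {
  cat(sprintf("<two_cutpoint_result> cutoffs = (%.4g, %.4g), chi2 = %.3f, groups %s\n",
              x$cutoffs[1], x$cutoffs[2], x$chi2,
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}
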