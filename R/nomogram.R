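#' Build a points-based nomogram from a Cox model
#'
#' Re-parameterizes per-level log-hazards into nomogram points: within
#' each predictor, the lowest-risk level gets 0 points and every level
#' L gets `100 * (beta_L - min beta) / B`, where B is the largest
#' within-predictor log-hazard range across all predictors (so exactly
#' one predictor spans the full 0-100 bar). The transformation is a
#' lossless affine re-scaling of the linear predictor:
#' `points_per_unit_beta = 100 / B`.
#'
#' @param model A `tsr_coxmodel` from [cox_fit()] or
#'   [cox_model_from_hrs()].
#' @return Object of class `tsr_nomogram`: `points` (named list of
#'   named per-level point vectors), `points_per_unit_beta`, and
#'   `baseline` (survival step function at the 0-point pattern, when
#'   the model carries one).
#' @examples
#' nomo <- build_nomogram(cox_model_from_hrs(bc_multivariable_hrs()))
#' nomo$points$n_status
#' @export
build_nomogram <- function(model) {
  stopifnot(inherits(model, "tsr_coxmodel"))
  co <- model$coefficients
  if (any(is.na(co$level)))
    stop("build_nomogram: only categorical (factor) predictors are supported",
         call. = FALSE)
  preds <- unique(co$predictor)
  ranges <- vapply(preds, function(v) {
    b <- co$beta[co$predictor == v]
    max(b) - min(b)
  }, numeric(1))
  B <- max(ranges)
  if (B <= 1e-12)
    stop("build_nomogram: degenerate model (all coefficients zero)",
         call. = FALSE)
  points <- lapply(preds, function(v) {
    sub <- co[co$predictor == v, ]
    setNames(100 * (sub$beta - min(sub$beta)) / B, sub$level)
  })
  names(points) <- preds
  structure(list(points = points, points_per_unit_beta = 100 / B,
                 baseline = model$baseline),
            class = "tsr_nomogram")
}

#' @export
print.tsr_nomogram <- function(x, ...) {
  cat("<tsr_nomogram> points per predictor level:\n")
  for (v in names(x$points))
    cat(sprintf("  %-12s %s\n", v,
                paste(sprintf("%s: %.1f", names(x$points[[v]]),
                              x$points[[v]]), collapse = ", ")))
  cat(sprintf("  (1 unit log-hazard = %.2f points%s)\n",
              x$points_per_unit_beta,
              if (is.null(x$baseline)) "; no baseline survival" else ""))
  invisible(x)
}

#' Total nomogram points for patients
#'
#' Sums the per-predictor points of each patient's levels. Internal
#' scoring keeps full precision (points are only rounded for display).
#'
#' @param nomo A [build_nomogram()] object.
#' @param covariates Data frame (or named list for a single patient)
#'   holding one column per nomogram predictor.
#' @return Numeric vector of total points.
#' @export
score_patients <- function(nomo, covariates) {
  stopifnot(inherits(nomo, "tsr_nomogram"))
  if (!is.data.frame(covariates))
    covariates <- as.data.frame(covariates, check.names = FALSE,
                                stringsAsFactors = FALSE)
  total <- rep(0, nrow(covariates))
  for (v in names(nomo$points)) {
    if (!v %in% names(covariates))
      stop("score_patients: missing predictor '", v, "'", call. = FALSE)
    lev <- as.character(covariates[[v]])
    pts <- nomo$points[[v]][lev]
    if (any(is.na(pts)))
      stop("score_patients: unknown level '",
           lev[which(is.na(pts))[1]], "' for predictor '", v, "'",
           call. = FALSE)
    total <- total + unname(pts)
  }
  total
}

#' Predicted survival from total nomogram points
#'
#' `S(t | x) = S0(t) ^ exp(total_points / points_per_unit_beta)`, where
#' `S0` is the baseline survival at the 0-point (lowest-risk) covariate
#' pattern. A patient with 0 total points therefore gets `S0(t)`
#' exactly, and the nomogram prediction coincides with the Cox model
#' prediction for every covariate pattern.
#'
#' @param nomo A [build_nomogram()] object carrying a baseline.
#' @param total_points Numeric vector of total points.
#' @param t Time in months (scalar), within the baseline support.
#' @return Survival probabilities in \[0, 1\].
#' @export
predict_survival <- function(nomo, total_points, t) {
  stopifnot(inherits(nomo, "tsr_nomogram"), length(t) == 1, t >= 0)
  if (is.null(nomo$baseline))
    stop("predict_survival: nomogram has no baseline survival", call. = FALSE)
  if (t > max(nomo$baseline$time))
    stop(sprintf("predict_survival: t = %g beyond baseline support (max %g)",
                 t, max(nomo$baseline$time)), call. = FALSE)
  s0 <- eval_surv_step(nomo$baseline$time, nomo$baseline$surv, t)
  s0 ^ exp(total_points / nomo$points_per_unit_beta)
}

#' Harrell's concordance index
#'
#' Probability that of a usable patient pair the one with the higher
#' risk score fails earlier; score ties count 1/2.
#'
#' @param scores Risk scores (higher = worse prognosis).
#' @param time,event Follow-up and event indicator.
#' @return List `(c_index, se, lower, upper)` with a 95% CI.
#' @export
c_index <- function(scores, time, event) {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  fit <- survival::concordance(survival::Surv(time, event) ~ scores,
                               reverse = TRUE)
  npairs <- sum(fit$count[c("concordant", "discordant", "tied.x")])
  if (npairs == 0)
    stop("c_index: no comparable pairs", call. = FALSE)
  se <- sqrt(fit$var)
  list(c_index = unname(fit$concordance), se = se,
       lower = unname(fit$concordance - qnorm(0.975) * se),
       upper = unname(fit$concordance + qnorm(0.975) * se))
}

#' Calibration of predicted survival against observed Kaplan-Meier
#'
#' Bins patients into `n_bins` equal-count groups by predicted survival
#' at horizon `t` and contrasts the mean prediction with the observed
#' KM estimate (and its 95% CI) in each bin. Bins where the KM estimate
#' is undefined at `t` are flagged.
#'
#' @param nomo A [build_nomogram()] with baseline.
#' @param data Clinical data frame holding the nomogram predictors plus
#'   time/event columns.
#' @param t Horizon in months (default 60).
#' @param n_bins Number of equal-count bins.
#' @param time,event Column names.
#' @return `data.frame` (bin, n, predicted, observed, lower, upper,
#'   flagged).
#' @export
calibration <- function(nomo, data, t = 60, n_bins = 4,
                        time = "time_months", event = "event") {
  pts <- score_patients(nomo, data)
  pred <- predict_survival(nomo, pts, t)
  qs <- quantile(pred, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(pred, breaks = unique(qs), include.lowest = TRUE)
  if (nlevels(bin) < n_bins)
    warning("calibration: fewer usable bins than requested (ties in predictions)",
            call. = FALSE)
  rows <- lapply(seq_len(nlevels(bin)), function(i) {
    sel <- which(as.integer(bin) == i)
    km <- km_estimate(data[[time]][sel], data[[event]][sel])
    obs <- tryCatch(eval_surv_step(km$table$time, km$table$surv, t),
                    error = function(e) NA_real_)
    lo <- eval_surv_step(km$table$time, km$table$lower, t)
    hi <- eval_surv_step(km$table$time, km$table$upper, t)
    flagged <- is.na(obs) || max(data[[time]][sel]) < t
    data.frame(bin = i, n = length(sel), predicted = mean(pred[sel]),
               observed = obs, lower = lo, upper = hi, flagged = flagged)
  })
  do.call(rbind, rows)
}

#' Compare the discrimination of two scores by ROC at a horizon
#'
#' The binary outcome is an event within `horizon` months; patients
#' censored before the horizon have unknown status and are excluded.
#' AUCs are empirical and compared by the paired DeLong test.
#'
#' @param score_a,score_b Two risk scores on the same patients.
#' @param time,event Follow-up and event indicator.
#' @param horizon Months (default 60).
#' @return List `(auc_a, auc_b, p, n)`.
#' @export
roc_compare <- function(score_a, score_b, time, event, horizon = 60) {
  known <- event == 1 & time <= horizon | time >= horizon
  outcome <- as.integer(event == 1 & time <= horizon)[known]
  if (length(unique(outcome)) < 2)
    stop("roc_compare: outcome has a single class at the horizon",
         call. = FALSE)
  a <- score_a[known]; b <- score_b[known]
  ra <- pROC::roc(outcome, a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(outcome, b, quiet = TRUE, direction = "<")
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(auc_a = as.numeric(pROC::auc(ra)), auc_b = as.numeric(pROC::auc(rb)),
       p = tst$p.value, n = sum(known))
}

#' Risk stratification by total nomogram points
#'
#' Scores the cohort, finds the optimal pair of total-point cutoffs by
#' the 3-group best-P search ([optimal_two_cutpoints()]), and assigns
#' risk groups I (total points <= cutoff1), II (<= cutoff2) and III
#' (> cutoff2).
#'
#' @param nomo A [build_nomogram()] object.
#' @param data Clinical data frame with nomogram predictors and
#'   time/event columns.
#' @param min_group_frac Minimum group fraction for the cutoff search.
#' @param time,event Column names.
#' @return Object of class `risk_strata`: `cutoffs`, `group` (factor
#'   I/II/III per patient), `total_points`, `chi2` of the 3-group
#'   search.
#' @export
stratify_risk <- function(nomo, data, min_group_frac = 0.10,
                          time = "time_months", event = "event") {
  pts <- score_patients(nomo, data)
  res <- optimal_two_cutpoints(pts, data[[time]], data[[event]],
                               min_group_frac = min_group_frac)
  grp <- cut(pts, breaks = c(-Inf, res$cutoffs, Inf),
             labels = c("I", "II", "III"), right = TRUE)
  structure(list(cutoffs = res$cutoffs, group = grp, total_points = pts,
                 chi2 = res$chi2, p_raw = res$p_raw,
                 group_sizes = table(grp)),
            class = "risk_strata")
}

#' @export
print.risk_strata <- function(x, ...) {
  cat(sprintf("<risk_strata> cutoffs = (%.1f, %.1f), groups I/II/III = %s, chi2 = %.1f\n",
              x$cutoffs[1], x$cutoffs[2],
              paste(x$group_sizes, collapse = "/"), x$chi2))
  invisible(x)
}
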