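#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson statistic (no Yates continuity correction; the
#' convention that reproduces the motivating cohort's printed
#' association P-values).
#'
#' @param counts r x c matrix of non-negative counts.
#' @return List `(chi2, df, p, expected)`.
#' @examples
#' pearson_chi2(rbind(c(74, 60), c(73, 33)))$p
#' @export
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) >= 2, ncol(counts) >= 2, all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("pearson_chi2: zero row or column total", call. = FALSE)
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, expected = ht$expected)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided exact P by hypergeometric enumeration.
#'
#' @param counts 2 x 2 matrix of counts.
#' @return Two-sided P-value.
#' @export
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)))
    stop("fisher_exact: table must be 2 x 2", call. = FALSE)
  fisher.test(counts)$p.value
}

#' Association test with conventional Fisher fallback
#'
#' Pearson chi-square unless any expected cell count is below 5 on a
#' 2 x 2 table, in which case Fisher's exact test is used.
#'
#' @param counts r x c count matrix.
#' @return List `(method, chi2, df, p)`; `chi2`/`df` are `NA` for
#'   Fisher.
#' @export
association_test <- function(counts) {
  res <- pearson_chi2(counts)
  if (all(dim(as.matrix(counts)) == c(2, 2)) && any(res$expected < 5)) {
    list(method = "fisher", chi2 = NA_real_, df = NA_real_,
         p = fisher_exact(counts))
  } else {
    list(method = "pearson", chi2 = res$chi2, df = res$df, p = res$p)
  }
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Follow-up times (>= 0).
#' @param event Event indicator (0/1); censoring at a time is handled
#'   after events at that time.
#' @return Object of class `km_curve` with a `table` data frame
#'   (`time`, `n_risk`, `n_event`, `surv`, `lower`, `upper`) and the
#'   underlying [survival::survfit] object.
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop("km_estimate: empty input", call. = FALSE)
  stopifnot(length(time) == length(event), all(time >= 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(fit, censored = TRUE)
  structure(list(table = data.frame(time = s$time, n_risk = s$n.risk,
                                    n_event = s$n.event, surv = s$surv,
                                    lower = s$lower, upper = s$upper),
                 fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d time points, final S = %.3f\n",
              nrow(x$table), min(x$table$surv)))
  invisible(x)
}

# Step-function evaluation of a KM/baseline curve at time t
# (right-continuous; S(0) = 1).
eval_surv_step <- function(times, surv, t) {
  vapply(t, function(tt) {
    if (tt < 0) stop("time must be >= 0", call. = FALSE)
    i <- findInterval(tt, times)
    if (i == 0) 1 else surv[i]
  }, numeric(1))
}

#' Log-rank test between survival curves
#'
#' @param time,event Follow-up and event indicator.
#' @param group Group labels (>= 2 non-empty groups).
#' @return List `(chi2, df, p)`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2)
    stop("logrank_test: need at least 2 non-empty groups", call. = FALSE)
  if (sum(event) == 0)
    stop("logrank_test: zero events overall", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  list(chi2 = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

# --- Cox model fitting with selection ---------------------------------

# Profile score test for adding `add` to the model with `current`
# covariates: evaluate the global score statistic at (beta_hat, 0).
cox_score_add <- function(data, time, event, current, add, ties) {
  f_cur <- cox_formula(time, event, current)
  f_new <- cox_formula(time, event, c(current, add))
  init <- rep(0, n_cox_coefs(data, c(current, add)))
  if (length(current)) {
    fit_cur <- survival::coxph(f_cur, data = data, ties = ties)
    init[seq_along(coef(fit_cur))] <- coef(fit_cur)
  }
  fit0 <- survival::coxph(f_new, data = data, ties = ties, init = init,
                          control = survival::coxph.control(iter.max = 0))
  df <- n_cox_coefs(data, add)
  # subtract the (zero) score contribution of the current block: at the
  # current MLE the score for current covariates vanishes, so the
  # global statistic at init equals the profile score test for `add`.
  stat <- fit0$score
  list(stat = stat, df = df,
       p = pchisq(stat, df, lower.tail = FALSE))
}

cox_formula <- function(time, event, covariates) {
  rhs <- if (length(covariates)) paste(sprintf("`%s`", covariates),
                                       collapse = " + ") else "1"
  as.formula(sprintf("survival::Surv(`%s`, `%s`) ~ %s", time, event, rhs))
}

n_cox_coefs <- function(data, covariates) {
  sum(vapply(covariates, function(v) {
    x <- data[[v]]
    if (is.factor(x)) nlevels(droplevels(x)) - 1L else 1L
  }, integer(1)))
}

#' Fit a Cox proportional-hazards model with variable selection
#'
#' Partial-likelihood fit (Breslow ties by default, matching the SPSS
#' convention of the motivating analysis) with the three selection
#' procedures used there: `enter` (all covariates), `forward` (score
#' test to enter) and `backward` (likelihood-ratio test to remove),
#' both stepwise procedures at significance level `alpha` (default
#' 0.10). Covariates with zero variance are excluded with a warning.
#'
#' @param data Data frame (e.g. a clinical table).
#' @param covariates Character vector of covariate column names
#'   (factors or numerics).
#' @param time,event Column names of follow-up time and event flag.
#' @param selection `"enter"`, `"forward"` or `"backward"`.
#' @param alpha Entry/removal significance level.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return Object of class `tsr_coxmodel`: the `survival::coxph` fit,
#'   a per-level coefficient table (`coefficients`: predictor, level,
#'   beta, hr, lower, upper, p; reference levels carry beta 0), the
#'   selected covariates, selection/ties tags, and the baseline
#'   survival step function at the lowest-risk covariate pattern.
#' @export
cox_fit <- function(data, covariates, time = "time_months",
                    event = "event",
                    selection = c("enter", "forward", "backward"),
                    alpha = 0.10, ties = c("breslow", "efron")) {
  selection <- match.arg(selection)
  ties <- match.arg(ties)
  stopifnot(length(covariates) >= 1)
  keep <- complete.cases(data[, c(covariates, time, event), drop = FALSE])
  data <- droplevels(data[keep, , drop = FALSE])
  if (sum(data[[event]]) < 1) stop("cox_fit: no events", call. = FALSE)

  const <- vapply(covariates, function(v) {
    x <- data[[v]]
    length(unique(x[!is.na(x)])) < 2
  }, logical(1))
  if (any(const)) {
    warning("cox_fit: excluding zero-variance covariate(s): ",
            paste(covariates[const], collapse = ", "), call. = FALSE)
    covariates <- covariates[!const]
  }
  if (!length(covariates))
    stop("cox_fit: no usable covariates", call. = FALSE)

  selected <- switch(selection,
    enter = covariates,
    forward = {
      cur <- character(0)
      repeat {
        pool <- setdiff(covariates, cur)
        if (!length(pool)) break
        tests <- lapply(pool, function(v)
          cox_score_add(data, time, event, cur, v, ties))
        ps <- vapply(tests, `[[`, numeric(1), "p")
        if (min(ps) < alpha) cur <- c(cur, pool[which.min(ps)]) else break
      }
      if (!length(cur))
        stop("cox_fit: forward selection admitted no covariate at alpha = ",
             alpha, call. = FALSE)
      cur
    },
    backward = {
      cur <- covariates
      repeat {
        if (length(cur) <= 1) break
        full <- survival::coxph(cox_formula(time, event, cur), data = data,
                                ties = ties)
        ps <- vapply(cur, function(v) {
          red <- survival::coxph(cox_formula(time, event, setdiff(cur, v)),
                                 data = data, ties = ties)
          lr <- 2 * (full$loglik[2] - red$loglik[length(red$loglik)])
          pchisq(lr, n_cox_coefs(data, v), lower.tail = FALSE)
        }, numeric(1))
        if (max(ps) >= alpha) cur <- setdiff(cur, cur[which.max(ps)])
        else break
      }
      cur
    })

  fit <- survival::coxph(cox_formula(time, event, selected), data = data,
                         ties = ties, x = TRUE, model = TRUE)
  if (is.null(fit$coefficients) || any(is.na(coef(fit))))
    stop("cox_fit: model did not converge (possible separation)",
         call. = FALSE)

  coefs <- cox_level_table(fit, data, selected)
  baseline <- cox_baseline_lowrisk(fit, data, selected, coefs)
  structure(list(fit = fit, coefficients = coefs, covariates = selected,
                 selection = selection, ties = ties,
                 baseline = baseline, data = data,
                 time = time, event = event),
            class = "tsr_coxmodel")
}

# Per-predictor per-level table including reference levels (beta 0).
cox_level_table <- function(fit, data, covariates) {
  sm <- summary(fit)$coefficients
  ci <- summary(fit)$conf.int
  rows <- list()
  for (v in covariates) {
    x <- data[[v]]
    if (is.factor(x)) {
      lv <- levels(x)
      rows[[v]] <- data.frame(
        predictor = v, level = lv,
        beta = c(0, sm[paste0(v, lv[-1]), "coef"]),
        hr = c(1, ci[paste0(v, lv[-1]), "exp(coef)"]),
        lower = c(NA, ci[paste0(v, lv[-1]), "lower .95"]),
        upper = c(NA, ci[paste0(v, lv[-1]), "upper .95"]),
        p = c(NA, sm[paste0(v, lv[-1]), "Pr(>|z|)"]),
        stringsAsFactors = FALSE)
    } else {
      rows[[v]] <- data.frame(
        predictor = v, level = NA_character_,
        beta = sm[v, "coef"], hr = ci[v, "exp(coef)"],
        lower = ci[v, "lower .95"], upper = ci[v, "upper .95"],
        p = sm[v, "Pr(>|z|)"], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Breslow baseline survival evaluated at the lowest-risk covariate
# pattern (each factor at its minimum-beta level).
cox_baseline_lowrisk <- function(fit, data, covariates, coefs) {
  nd <- data[1, covariates, drop = FALSE]
  for (v in covariates) {
    if (is.factor(data[[v]])) {
      sub <- coefs[coefs$predictor == v, ]
      nd[[v]] <- factor(sub$level[which.min(sub$beta)],
                        levels = levels(data[[v]]))
    } else {
      nd[[v]] <- min(data[[v]], na.rm = TRUE)
    }
  }
  sf <- survival::survfit(fit, newdata = nd, type = "breslow")
  list(time = sf$time, surv = as.numeric(sf$surv), pattern = nd)
}

#' @export
print.tsr_coxmodel <- function(x, ...) {
  cat(sprintf("<tsr_coxmodel> selection = %s, ties = %s, n = %d, events = %d\n",
              x$selection, x$ties, x$fit$n, x$fit$nevent))
  print(transform(x$coefficients,
                  hr = round(hr, 3), beta = round(beta, 3),
                  p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Construct a Cox-model shell from published hazard ratios
#'
#' Builds the per-level coefficient table of a `tsr_coxmodel` directly
#' from per-predictor hazard-ratio vectors (reference level HR 1), so a
#' nomogram can be derived from printed results without refitting. The
#' shell has no baseline survival and cannot predict.
#'
#' @param hrs Named list of named numeric HR vectors, e.g.
#'   [bc_multivariable_hrs()].
#' @return A `tsr_coxmodel` (without `fit`, `baseline`, `data`).
#' @examples
#' build_nomogram(cox_model_from_hrs(bc_multivariable_hrs()))
#' @export
cox_model_from_hrs <- function(hrs) {
  stopifnot(is.list(hrs), length(hrs) >= 1)
  rows <- lapply(names(hrs), function(v) {
    h <- hrs[[v]]
    stopifnot(is.numeric(h), !is.null(names(h)), all(h > 0))
    data.frame(predictor = v, level = names(h), beta = log(h), hr = h,
               lower = NA_real_, upper = NA_real_, p = NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(list(fit = NULL, coefficients = do.call(rbind, rows),
                 covariates = names(hrs), selection = "published",
                 ties = NA_character_, baseline = NULL, data = NULL),
            class = "tsr_coxmodel")
}

#' Per-subgroup hazard ratios of an exposure (forest table)
#'
#' For each level of a stratifying factor, fits the univariate Cox model
#' of the exposure within the stratum and reports HR, 95% CI and P.
#' Strata without events (or without both exposure levels) are reported
#' as `NA` with a warning, since their confidence intervals are
#' unbounded.
#'
#' @param data Clinical data frame.
#' @param stratifier Column name of the stratifying factor.
#' @param exposure Column name of the exposure (e.g. TSR group).
#' @param time,event Column names.
#' @return `data.frame` (subgroup, n, events, hr, lower, upper, p).
#' @export
subgroup_forest <- function(data, stratifier, exposure = "tsr_group",
                            time = "time_months", event = "event") {
  stopifnot(stratifier %in% names(data), exposure %in% names(data))
  levs <- levels(as.factor(data[[stratifier]]))
  rows <- lapply(levs, function(lv) {
    sub <- droplevels(data[data[[stratifier]] == lv, , drop = FALSE])
    base <- data.frame(subgroup = lv, n = nrow(sub),
                       events = sum(sub[[event]]),
                       hr = NA_real_, lower = NA_real_, upper = NA_real_,
                       p = NA_real_, stringsAsFactors = FALSE)
    if (sum(sub[[event]]) < 1 ||
        length(unique(sub[[exposure]])) < 2) {
      warning(sprintf("subgroup_forest: HR undefined in stratum '%s'", lv),
              call. = FALSE)
      return(base)
    }
    f <- survival::coxph(cox_formula(time, event, exposure), data = sub,
                         ties = "breslow")
    s <- summary(f)
    base$hr <- s$conf.int[1, "exp(coef)"]
    base$lower <- s$conf.int[1, "lower .95"]
    base$upper <- s$conf.int[1, "upper .95"]
    base$p <- s$coefficients[1, "Pr(>|z|)"]
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
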