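# Prognostic performance statistics: ROC/Youden diagnostics with exact
# binomial intervals, Harrell's concordance on censored data, Kaplan-Meier
# and Cox analyses, nested logistic risk models, and IDI/NRI
# reclassification statistics.

#' ROC curve and area under it
#'
#' Trapezoidal AUC over the empirical ROC curve; tied scores contribute
#' diagonal segments, so the area equals the rank-sum (Mann-Whitney)
#' statistic scaled by the product of group sizes.
#'
#' @param scores risk scores (higher = more case-like)
#' @param labels case/control labels
#' @return list with `auc` and `curve` (data.frame fpr, tpr, threshold)
#' @export
roc_auc <- function(scores, labels) {
  case <- as_case_flag(labels)
  if (!any(case) || all(case)) stop("both classes required for ROC analysis")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[case] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!case] >= t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  list(auc = auc, curve = curve)
}

#' Youden-index optimal threshold
#'
#' Scans midpoints between consecutive distinct scores (positive call:
#' score strictly above the threshold) and returns the one maximizing
#' J = sensitivity + specificity - 1. Ties are broken toward higher
#' specificity, then the lower threshold. All-equal scores are degenerate:
#' J = 0 at that value, flagged.
#'
#' @inheritParams roc_auc
#' @return list: `threshold`, `J`, `sensitivity`, `specificity`,
#'   `degenerate`
#' @export
youden_threshold <- function(scores, labels) {
  case <- as_case_flag(labels)
  if (!any(case) || all(case)) stop("both classes required")
  u <- sort(unique(scores))
  if (length(u) == 1) {
    return(list(threshold = u, J = 0, sensitivity = 0, specificity = 1,
                degenerate = TRUE))
  }
  # midpoints between distinct scores, plus the two trivial classifiers
  # (everyone negative / everyone positive) so J never falls below 0
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  sens <- vapply(cand, function(t) mean(scores[case] > t), numeric(1))
  spec <- vapply(cand, function(t) mean(scores[!case] <= t), numeric(1))
  J <- sens + spec - 1
  best <- order(-J, -spec, cand)[1]
  list(threshold = cand[best], J = J[best], sensitivity = sens[best],
       specificity = spec[best], degenerate = FALSE)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Interval from Beta quantiles: lower `qbeta(alpha/2; x, n - x + 1)` (0
#' when x = 0), upper `qbeta(1 - alpha/2; x + 1, n - x)` (1 when x = n).
#'
#' @param successes,n counts, `0 <= successes <= n`
#' @param conf confidence level
#' @return c(lo, hi)
#' @export
exact_binomial_ci <- function(successes, n, conf = 0.95) {
  if (n < 1 || successes < 0 || successes > n) stop("invalid counts")
  alpha <- 1 - conf
  lo <- if (successes == 0) 0 else stats::qbeta(alpha / 2, successes, n - successes + 1)
  hi <- if (successes == n) 1 else stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lo, hi)
}

#' Positive likelihood ratio
#'
#' sensitivity / (1 - specificity); perfect specificity gives `Inf`.
#' @param sensitivity,specificity fractions
#' @export
positive_likelihood_ratio <- function(sensitivity, specificity) {
  check_prob(c(sensitivity, specificity), "sensitivity/specificity")
  if (specificity >= 1) return(structure(Inf, infinite = TRUE))
  sensitivity / (1 - specificity)
}

#' Diagnostic summary at a threshold
#'
#' Confusion counts (positive call: score strictly above the threshold),
#' sensitivity and specificity with exact binomial 95% intervals, and the
#' positive likelihood ratio.
#'
#' @inheritParams roc_auc
#' @param threshold classification cut-off
#' @param conf confidence level for the intervals
#' @return list of class `diagnostic_summary`
#' @export
diagnostic_summary <- function(scores, labels, threshold, conf = 0.95) {
  case <- as_case_flag(labels)
  pos <- scores > threshold
  tp <- sum(pos & case); fn <- sum(!pos & case)
  tn <- sum(!pos & !case); fp <- sum(pos & !case)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  structure(list(threshold = threshold,
                 counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 sensitivity = sens, sensitivity_ci = exact_binomial_ci(tp, tp + fn, conf),
                 specificity = spec, specificity_ci = exact_binomial_ci(tn, tn + fp, conf),
                 plr = positive_likelihood_ratio(sens, spec), conf = conf),
            class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf("threshold %.4g: sens %.1f%% (%.1f-%.1f), spec %.1f%% (%.1f-%.1f), LR+ %.3g\n",
              x$threshold, 100 * x$sensitivity, 100 * x$sensitivity_ci[1],
              100 * x$sensitivity_ci[2], 100 * x$specificity,
              100 * x$specificity_ci[1], 100 * x$specificity_ci[2], x$plr))
  invisible(x)
}

#' Harrell's concordance for censored outcomes
#'
#' Over usable pairs (distinct observed times where the earlier time is an
#' event), c is the fraction of pairs in which the higher score belongs to
#' the earlier event, counting tied scores as 1/2. The confidence interval
#' comes from the asymptotic U-statistic variance of Somers' D
#' (c = (D + 1)/2), estimated from per-subject mean pair contributions.
#'
#' @param scores risk scores (higher = earlier event expected)
#' @param time observed follow-up times
#' @param event event indicator (1 = event, 0 = censored)
#' @param conf confidence level
#' @return list: `c`, `ci`, `se`, `n_pairs`
#' @export
harrell_c <- function(scores, time, event, conf = 0.95) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  dt <- outer(time, time, "-")           # t_i - t_j
  ei <- matrix(event == 1, n, n)         # row subject has event
  usable <- (dt < 0 & ei) | (dt > 0 & t(ei))  # earlier of the two has event
  diag(usable) <- FALSE
  if (!any(usable)) stop("no usable pairs (all observations censored?)")
  ds <- outer(scores, scores, "-")
  # pair contribution from row subject's viewpoint: +1 concordant, 0.5 tie
  conc <- ifelse(dt < 0, sign(ds), sign(-ds))  # row subject earlier -> should score higher
  contrib <- (conc + 1) / 2
  contrib[!usable] <- NA
  cstat <- mean(contrib, na.rm = TRUE)
  # U-statistic delta-method variance of D = 2c - 1
  d_i <- rowMeans(2 * contrib - 1, na.rm = TRUE)
  d_i <- d_i[is.finite(d_i)]
  var_d <- 4 * stats::var(d_i) / length(d_i)
  se_c <- sqrt(var_d) / 2
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(c = cstat, ci = clamp(c(cstat - z * se_c, cstat + z * se_c), 0, 1),
       se = se_c, n_pairs = sum(usable) / 2)
}

#' Kaplan-Meier cumulative event curves by group
#'
#' Product-limit estimate per group, tabulated as the cumulative event
#' percentage 100 * (1 - S(t)).
#'
#' @param time,event survival outcome
#' @param group dichotomous grouping (e.g. score above/below threshold)
#' @return data.frame: group, time, n_risk, n_event, surv, cum_event_pct
#' @export
km_estimate <- function(time, event, group) {
  g <- factor(group)
  out <- do.call(rbind, lapply(levels(g), function(lev) {
    i <- g == lev
    fit <- survival::survfit(survival::Surv(time[i], event[i]) ~ 1)
    data.frame(group = lev, time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, surv = fit$surv,
               cum_event_pct = 100 * (1 - fit$surv),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Breslow tie handling (Efron available via
#' `ties`); returns hazard ratios with Wald confidence intervals and
#' p-values.
#'
#' @param time,event survival outcome
#' @param covariates data.frame of numeric covariates
#' @param ties tie-handling method
#' @param conf confidence level
#' @return list with `table` (term, coef, hr, lo, hi, se, p) and `fit`
#' @export
cox_fit <- function(time, event, covariates, ties = c("breslow", "efron"),
                    conf = 0.95) {
  ties <- match.arg(ties)
  if (sum(event) < 1) stop("at least one event required")
  const <- vapply(covariates, function(x) length(unique(x)) == 1L, logical(1))
  if (any(const)) {
    stop(sprintf("constant covariate(s): %s",
                 paste(names(covariates)[const], collapse = ", ")))
  }
  df <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = ties,
                         control = survival::coxph.control(eps = 1e-9, iter.max = 50))
  if (!is.null(fit$info) && any(grepl("infinite", fit$info))) {
    stop("monotone likelihood: a coefficient diverged")
  }
  sm <- summary(fit, conf.int = conf)
  tab <- data.frame(term = rownames(sm$coefficients),
                    coef = sm$coefficients[, "coef"],
                    hr = sm$coefficients[, "exp(coef)"],
                    lo = sm$conf.int[, 3], hi = sm$conf.int[, 4],
                    se = sm$coefficients[, "se(coef)"],
                    p = sm$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab, fit = fit)
}

#' Backwards step-down Cox covariate selection
#'
#' Repeatedly refits the Cox model, removing the covariate with the
#' largest Wald p-value while that p-value is at or above `removal_alpha`,
#' until every remaining covariate is significant (or none remain).
#' Deterministic; the removal order is reported.
#'
#' @inheritParams cox_fit
#' @param removal_alpha stay-in significance level
#' @return list: `retained` (names), `fit` (final [cox_fit()] or NULL),
#'   `trace` (removal order with p-values)
#' @export
stepwise_cox <- function(time, event, covariates, removal_alpha = 0.05,
                         ties = "breslow") {
  current <- names(covariates)
  trace <- data.frame(removed = character(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  fit <- NULL
  while (length(current) > 0) {
    fit <- cox_fit(time, event, covariates[current], ties = ties)
    worst <- which.max(fit$table$p)
    if (fit$table$p[worst] < removal_alpha) break
    trace <- rbind(trace, data.frame(removed = fit$table$term[worst],
                                     p = fit$table$p[worst],
                                     stringsAsFactors = FALSE))
    current <- setdiff(current, fit$table$term[worst])
    fit <- NULL
  }
  list(retained = current, fit = fit, trace = trace)
}

# logistic fit robust to separation: ridge fallback with warning
safe_logistic <- function(fml, data) {
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated) {
    warning("separation in logistic model; ridge-penalized refit")
    X <- stats::model.matrix(fml, data)
    y <- stats::model.response(stats::model.frame(fml, data))
    beta <- ridge_logistic(X, y)
    return(list(fitted = as.numeric(stats::plogis(X %*% beta)),
                coefficients = beta, separated = TRUE))
  }
  list(fitted = as.numeric(stats::fitted(fit)), coefficients = stats::coef(fit),
       separated = FALSE, glm = fit)
}

#' Nested logistic risk models
#'
#' Fits the three risk models compared by reclassification analysis:
#' model 1 regresses case status on study centre and the Framingham score;
#' model 2 adds the peptide-pattern score; model 3 adds the composite
#' score. A single-centre cohort drops the centre terms automatically;
#' separation falls back to a ridge-penalized fit with a warning.
#'
#' @param labels case/control labels
#' @param centre study-centre identifier (categorical)
#' @param fcvrs Framingham 10-year risk score (input covariate)
#' @param pattern_score,composite pattern and composite scores (either may
#'   be NULL to skip its model)
#' @return list of fitted probability vectors `p1`, `p2`, `p3` plus the
#'   fitted model objects
#' @export
nested_logistic_models <- function(labels, centre, fcvrs,
                                   pattern_score = NULL, composite = NULL) {
  case <- as_case_flag(labels)
  df <- data.frame(y = as.integer(case), fcvrs = fcvrs)
  base_terms <- "fcvrs"
  if (length(unique(centre)) > 1) {
    df$centre <- factor(centre)
    base_terms <- c("centre", "fcvrs")
  }
  fit_of <- function(extra_name, extra) {
    if (is.null(extra)) return(NULL)
    df[[extra_name]] <- extra
    safe_logistic(stats::as.formula(
      paste("y ~", paste(c(base_terms, extra_name), collapse = " + "))), df)
  }
  m1 <- safe_logistic(stats::as.formula(
    paste("y ~", paste(base_terms, collapse = " + "))), df)
  m2 <- fit_of("pattern", pattern_score)
  m3 <- fit_of("composite", composite)
  list(p1 = m1$fitted, p2 = if (!is.null(m2)) m2$fitted,
       p3 = if (!is.null(m3)) m3$fitted,
       models = list(m1 = m1, m2 = m2, m3 = m3))
}

#' Integrated discrimination and net reclassification improvement
#'
#' IDI is the change in discrimination slope: the mean risk-probability
#' gain of the new model in events minus the mean gain in non-events.
#' Categorical NRI uses the risk bands `[0, lo)`, `[lo, hi)`, `[hi, 1]`
#' (defaults 10% and 20%): net upward movement in events minus net upward
#' movement in non-events. Standard errors treat events and non-events as
#' independent samples; two-sided z-tests.
#'
#' @param p_old,p_new predicted event probabilities under the reference
#'   and extended models
#' @param labels case/control (event) labels
#' @param categories ascending risk-category boundaries
#' @return list of class `reclass_report`: `idi`, `idi_se`, `idi_p`,
#'   `nri`, `nri_se`, `nri_p`, `categories`, and per-group `movement`
#'   tables (old category x new category)
#' @export
idi_nri <- function(p_old, p_new, labels, categories = c(0.10, 0.20)) {
  check_prob(p_old, "p_old"); check_prob(p_new, "p_new")
  case <- as_case_flag(labels)
  if (!any(case) || all(case)) stop("both classes required")
  ne <- sum(case); nn <- sum(!case)

  d <- p_new - p_old
  idi <- mean(d[case]) - mean(d[!case])
  idi_se <- sqrt(stats::var(d[case]) / ne + stats::var(d[!case]) / nn)
  idi_p <- if (idi_se > 0) 2 * stats::pnorm(-abs(idi / idi_se)) else NA_real_

  brks <- c(-Inf, categories, Inf)
  labs <- paste0("cat", seq_len(length(categories) + 1))
  co <- cut(p_old, brks, right = FALSE, labels = labs)
  cn <- cut(p_new, brks, right = FALSE, labels = labs)
  up <- as.integer(cn) > as.integer(co)
  dn <- as.integer(cn) < as.integer(co)
  pu_e <- mean(up[case]); pd_e <- mean(dn[case])
  pu_n <- mean(up[!case]); pd_n <- mean(dn[!case])
  nri <- (pu_e - pd_e) - (pu_n - pd_n)
  nri_se <- sqrt((pu_e + pd_e - (pu_e - pd_e)^2) / ne +
                   (pu_n + pd_n - (pu_n - pd_n)^2) / nn)
  nri_p <- if (nri_se > 0) 2 * stats::pnorm(-abs(nri / nri_se)) else NA_real_

  structure(list(idi = idi, idi_se = idi_se, idi_p = idi_p,
                 nri = nri, nri_se = nri_se, nri_p = nri_p,
                 categories = categories,
                 movement = list(events = table(old = co[case], new = cn[case]),
                                 nonevents = table(old = co[!case], new = cn[!case]))),
            class = "reclass_report")
}

#' @export
print.reclass_report <- function(x, ...) {
  cat(sprintf("IDI %.3f +/- %.3f (P = %.4g); NRI %.3f +/- %.3f (P = %.4g)\n",
              x$idi, x$idi_se, x$idi_p, x$nri, x$nri_se, x$nri_p))
  invisible(x)
}
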