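# Prognostic statistics: ROC/Youden against brute force, exact binomial
# intervals against binom.test and by coverage, Harrell's c against pair
# enumeration, KM/Cox against closed forms and planted generators, nested
# logistic models, and IDI/NRI arithmetic.

test_that("AUC equals the rank-sum statistic and behaves at the extremes", {
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))$auc, 1.0)
  # rank-sum identity on random data with ties
  set.seed(1)
  for (rep in 1:10) {
    sc <- sample(1:8, 30, replace = TRUE)  # heavy ties
    lab <- rbinom(30, 1, 0.5)
    if (sum(lab) %in% c(0, 30)) next
    n1 <- sum(lab); n0 <- 30 - n1
    u <- sum(rank(sc)[lab == 1]) - n1 * (n1 + 1) / 2
    expect_equal(roc_auc(sc, lab)$auc, u / (n1 * n0), tolerance = 1e-12)
  }
  # independent scores: AUC near 1/2
  set.seed(2)
  auc0 <- roc_auc(rnorm(4000), rbinom(4000, 1, 0.5))$auc
  expect_lt(abs(auc0 - 0.5), 0.03)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
  # agreement with an independent ROC implementation
  set.seed(3)
  sc <- rnorm(60); lab <- rbinom(60, 1, 0.4)
  expect_equal(roc_auc(sc, lab)$auc,
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("Youden threshold equals the exhaustive scan on random instances", {
  # clean split: controls {1,2}, cases {3,4} -> threshold 2.5, J = 1
  y <- youden_threshold(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(y$threshold, 2.5)
  expect_equal(y$J, 1)
  set.seed(4)
  for (rep in 1:25) {
    n <- sample(10:200, 1)
    sc <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    lab <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (sum(lab) %in% c(0, n)) next
    got <- youden_threshold(sc, lab)
    expect_equal(got$J, brute_force_youden_J(sc, lab), tolerance = 1e-12)
    # reported sens/spec consistent with the reported threshold
    expect_equal(got$sensitivity, mean(sc[lab == 1] > got$threshold))
    expect_equal(got$specificity, mean(sc[lab == 0] <= got$threshold))
  }
  # degenerate: all scores equal
  d <- youden_threshold(rep(3, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(d$J, 0)
  expect_equal(d$threshold, 3)
  expect_true(d$degenerate)
})

test_that("Clopper-Pearson intervals match binom.test and achieve coverage", {
  for (x in c(0, 1, 17, 31, 42)) {
    ci <- exact_binomial_ci(x, 42)
    ref <- stats::binom.test(x, 42)$conf.int
    expect_equal(ci, as.numeric(ref), tolerance = 1e-10)
  }
  expect_equal(exact_binomial_ci(0, 10)[1], 0)
  expect_equal(exact_binomial_ci(10, 10)[2], 1)
  expect_error(exact_binomial_ci(5, 4), "invalid")
  # coverage at n = 42 over 10^4 replicates
  set.seed(5)
  for (p in c(0.1, 0.5, 0.9)) {
    x <- stats::rbinom(1e4, 42, p)
    lo <- ifelse(x == 0, 0, stats::qbeta(0.025, x, 42 - x + 1))
    hi <- ifelse(x == 42, 1, stats::qbeta(0.975, x + 1, 42 - x))
    expect_gte(mean(lo <= p & p <= hi), 0.95)
  }
})

test_that("positive likelihood ratio follows its definition and edge cases", {
  expect_equal(positive_likelihood_ratio(0.5, 0), 0.5)
  expect_equal(positive_likelihood_ratio(0.738, 0.738), 0.738 / 0.262)
  inf <- positive_likelihood_ratio(0.9, 1)
  expect_true(is.infinite(inf))
  expect_true(attr(inf, "infinite"))
  expect_error(positive_likelihood_ratio(1.2, 0.5), "\\[0, 1\\]")
})

test_that("diagnostic summary counts and intervals are internally consistent", {
  sc <- c(0.2, 0.3, 0.6, 0.9, 0.1, 0.25, 0.55, 0.05)
  lab <- c(1, 1, 1, 1, 0, 0, 0, 0)
  d <- diagnostic_summary(sc, lab, threshold = 0.4)
  expect_equal(unname(d$counts), c(2, 1, 3, 2))  # TP FP TN FN
  expect_equal(d$sensitivity, 2 / 4)
  expect_equal(d$specificity, 3 / 4)
  expect_true(d$sensitivity_ci[1] <= d$sensitivity &&
                d$sensitivity <= d$sensitivity_ci[2])
  expect_true(d$specificity_ci[1] <= d$specificity &&
                d$specificity <= d$specificity_ci[2])
  expect_equal(d$plr, (2 / 4) / (1 - 3 / 4))
})

test_that("Harrell's c matches all-pairs enumeration and an independent implementation", {
  # perfectly ordered, uncensored
  expect_equal(harrell_c(10:1, 1:10, rep(1, 10))$c, 1.0)
  set.seed(6)
  for (rep in 1:6) {
    n <- 20
    sc <- round(rnorm(n), 1)
    tm <- round(rexp(n, 0.3), 1) + 0.1
    ev <- rbinom(n, 1, 0.6)
    if (sum(ev) == 0) ev[1] <- 1
    got <- harrell_c(sc, tm, ev)
    expect_equal(got$c, brute_force_c(sc, tm, ev), tolerance = 1e-12)
  }
  # survival::concordance as an independent oracle; tie-free times, since
  # a tied-time event/censored pair is usable there but excluded here
  for (rep in 1:4) {
    n <- 25
    sc <- rnorm(n); tm <- rexp(n, 0.3); ev <- rbinom(n, 1, 0.6)
    if (sum(ev) == 0) ev[1] <- 1
    cf <- survival::concordance(survival::Surv(tm, ev) ~ sc, reverse = TRUE)
    expect_equal(harrell_c(sc, tm, ev)$c, as.numeric(cf$concordance),
                 tolerance = 1e-9)
  }
  expect_error(harrell_c(1:5, 1:5, rep(0, 5)), "usable")
})

test_that("without censoring and two time points, c reduces to the AUC", {
  set.seed(7)
  sc <- rnorm(40)
  lab <- rbinom(40, 1, 0.5)
  # cases fail at t=1, controls at t=2, everyone observed
  tm <- ifelse(lab == 1, 1, 2)
  expect_equal(harrell_c(sc, tm, rep(1, 40))$c, roc_auc(sc, lab)$auc,
               tolerance = 1e-12)
})

test_that("Harrell c confidence interval brackets the estimate sensibly", {
  set.seed(8)
  n <- 120
  risk <- rnorm(n)
  tm <- rexp(n, 0.2 * exp(0.8 * risk))
  ev <- as.integer(tm < 5); tm <- pmin(tm, 5)
  h <- harrell_c(risk, tm, ev)
  expect_true(h$ci[1] < h$c && h$c < h$ci[2])
  expect_gt(h$c, 0.6)  # real signal
  expect_gt(h$se, 0)
})

test_that("Kaplan-Meier output matches the empirical CDF when nothing is censored", {
  tm <- c(1, 2, 2, 3, 5); ev <- rep(1, 5)
  km <- km_estimate(tm, ev, rep("all", 5))
  ecdf_vals <- sapply(km$time, function(t) mean(tm <= t))
  expect_equal(km$cum_event_pct / 100, ecdf_vals, tolerance = 1e-12)
  # no events: flat at zero
  km0 <- km_estimate(c(2, 3, 4), c(0, 0, 0), rep("g", 3))
  expect_true(all(km0$cum_event_pct == 0))
  # order invariance
  set.seed(9)
  tm2 <- rexp(30); ev2 <- rbinom(30, 1, 0.7); gr <- rep(c("a", "b"), 15)
  perm <- sample(30)
  expect_equal(km_estimate(tm2, ev2, gr),
               km_estimate(tm2[perm], ev2[perm], gr[perm]))
})

test_that("Cox regression recovers a planted hazard ratio and nulls out noise", {
  set.seed(10)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  tm <- rexp(n, 0.1 * 3^x)  # true HR 3, no censoring
  fit <- cox_fit(tm, rep(1, n), data.frame(x = x))
  expect_gt(fit$table$hr, 2.5)
  expect_lt(fit$table$hr, 3.6)
  # independent covariate: HR near 1
  z <- rnorm(n)
  fit0 <- cox_fit(rexp(n, 0.1), rep(1, n), data.frame(z = z))
  expect_lt(abs(log(fit0$table$hr)), 0.2)
  expect_gt(fit0$table$p, 0.01)
  expect_error(cox_fit(tm, rep(1, n), data.frame(k = rep(2, n))), "constant")
})

test_that("duplicating every subject keeps the Cox HR and halves the variance", {
  set.seed(11)
  n <- 150
  x <- rnorm(n)
  tm <- rexp(n, 0.1 * exp(0.5 * x))
  ev <- rep(1, n)
  f1 <- cox_fit(tm, ev, data.frame(x = x))
  f2 <- cox_fit(rep(tm, 2), rep(ev, 2), data.frame(x = rep(x, 2)))
  expect_equal(f2$table$coef, f1$table$coef, tolerance = 1e-6)
  expect_equal(f2$table$se^2, f1$table$se^2 / 2, tolerance = 0.01)
})

test_that("backwards step-down retains planted predictors and drops noise", {
  set.seed(12)
  n <- 500
  planted <- rnorm(n)
  noise <- matrix(rnorm(n * 4), ncol = 4,
                  dimnames = list(NULL, paste0("n", 1:4)))
  tm <- rexp(n, 0.1 * exp(0.9 * planted))
  ev <- as.integer(tm < 8); tm <- pmin(tm, 8)
  cov <- data.frame(planted = planted, noise)
  sw <- stepwise_cox(tm, ev, cov)
  expect_true("planted" %in% sw$retained)
  expect_true(all(sw$fit$table$p < 0.05))
  expect_true(all(sw$trace$p >= 0.05))
  # strong covariates are never removed
  tm2 <- rexp(n, 0.1 * exp(0.8 * planted + 0.8 * noise[, 1]))
  sw2 <- stepwise_cox(pmin(tm2, 8), as.integer(tm2 < 8),
                      data.frame(planted = planted, n1 = noise[, 1]))
  expect_setequal(sw2$retained, c("planted", "n1"))
  expect_equal(nrow(sw2$trace), 0)
  # empty candidate set
  sw0 <- stepwise_cox(tm, ev, data.frame()[seq_len(n), , drop = FALSE])
  expect_length(sw0$retained, 0)
})

test_that("nested logistic models recover coefficients and handle degeneracies", {
  set.seed(13)
  n <- 600
  centre <- sample(c("A", "B"), n, replace = TRUE)
  fcvrs <- runif(n)
  score <- rnorm(n)
  eta <- -1 + 1.5 * fcvrs + 0.8 * score + 0.3 * (centre == "B")
  y <- rbinom(n, 1, stats::plogis(eta))
  nm <- nested_logistic_models(y, centre, fcvrs, pattern_score = score)
  cf <- nm$models$m2$coefficients
  se <- summary(nm$models$m2$glm)$coefficients[, "Std. Error"]
  truth <- c(-1, 0.3, 1.5, 0.8)
  expect_true(all(abs(cf - truth) < 2.5 * se))
  # extra score identical to an existing covariate: fits coincide
  nm2 <- nested_logistic_models(y, centre, fcvrs, pattern_score = fcvrs)
  expect_equal(nm2$p1, nm2$p2, tolerance = 1e-6)
  # single centre: centre terms dropped, model still fits
  nm3 <- nested_logistic_models(y, rep("A", n), fcvrs)
  expect_false("centreB" %in% names(nm3$models$m1$coefficients))
  expect_length(nm3$p1, n)
})

test_that("IDI and NRI follow their definitions, including the movement example", {
  # no change in predictions: both zero
  set.seed(14)
  p <- runif(40); lab <- rbinom(40, 1, 0.5)
  r0 <- idi_nri(p, p, lab)
  expect_equal(r0$idi, 0)
  expect_equal(r0$nri, 0)

  # constructed movement: events 2 up / 1 down of 10,
  # non-events 1 up / 3 down of 10 -> NRI = (0.2-0.1) - (0.1-0.3) = 0.30
  p_old <- c(rep(0.05, 10), rep(0.15, 10))
  p_new <- p_old
  p_new[1:2] <- 0.15     # events up
  p_new[3] <- 0.05 - 0.01 # stays low (no category change)
  p_old[3] <- 0.12; p_new[3] <- 0.05  # event down
  p_new[11] <- 0.25      # non-event up
  p_new[12:14] <- 0.05   # non-events down
  lab2 <- rep(c(1, 0), each = 10)
  r1 <- idi_nri(p_old, p_new, lab2)
  expect_equal(r1$nri, 0.30)
  expect_equal(sum(r1$movement$events), 10)
  expect_equal(sum(r1$movement$nonevents), 10)

  # IDI equals the difference in discrimination slopes, computed directly
  set.seed(15)
  po <- runif(60); pn <- stats::plogis(stats::qlogis(po) + rnorm(60, 0, 0.5))
  lb <- rbinom(60, 1, po)
  if (sum(lb) %in% c(0, 60)) lb[1:2] <- c(0, 1)
  slope <- function(pr) mean(pr[lb == 1]) - mean(pr[lb == 0])
  r2 <- idi_nri(po, pn, lb)
  expect_equal(r2$idi, slope(pn) - slope(po), tolerance = 1e-12)

  # exchanging old and new flips the signs
  r3 <- idi_nri(pn, po, lb)
  expect_equal(r3$idi, -r2$idi)
  expect_equal(r3$nri, -r2$nri)
  expect_equal(r3$idi_se, r2$idi_se)
})

test_that("risk-category boundaries are closed on the left", {
  # 0.10 is intermediate, 0.20 is high
  p_old <- c(0.0999, 0.10, 0.1999, 0.20)
  p_new <- c(0.10, 0.0999, 0.20, 0.1999)
  lab <- c(1, 1, 0, 0)
  r <- idi_nri(p_old, p_new, lab)
  # events: one up (0.0999->0.10), one down; non-events: one up, one down
  expect_equal(unname(r$movement$events["cat1", "cat2"]), 1)
  expect_equal(unname(r$movement$events["cat2", "cat1"]), 1)
  expect_equal(unname(r$movement$nonevents["cat2", "cat3"]), 1)
  expect_equal(unname(r$movement$nonevents["cat3", "cat2"]), 1)
  expect_equal(r$nri, 0)
})

test_that("evaluation statistics are invariant to sample reordering", {
  set.seed(16)
  n <- 80
  sc <- rnorm(n); lab <- rbinom(n, 1, 0.5)
  tm <- rexp(n, 0.3); ev <- rbinom(n, 1, 0.7)
  perm <- sample(n)
  expect_equal(roc_auc(sc, lab)$auc, roc_auc(sc[perm], lab[perm])$auc)
  expect_equal(youden_threshold(sc, lab), youden_threshold(sc[perm], lab[perm]))
  expect_equal(harrell_c(sc, tm, ev)$c, harrell_c(sc[perm], tm[perm], ev[perm])$c)
})
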