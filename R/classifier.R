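# SVM peptide-pattern scoring and the linear composite risk score.
#
# The pattern classifier places each sample in an N-dimensional space of
# log2 peptide intensities and scores it by its signed distance to a
# maximal-margin separating hyperplane fitted with a soft-margin radial
# basis function SVM. Positive scores are case-like by convention.

#' Build the SVM feature table from an amplitude matrix
#'
#' Features are log2 amplitudes of the panel peptides; an undetected value
#' (amplitude 0) is encoded as feature 0. Note the deliberate collision:
#' amplitude 1 also maps to 0. `undetected = "log1p"` instead uses
#' log2(amplitude + 1), which is collision-free.
#'
#' @param matrix amplitude matrix (samples x peptides)
#' @param panel_ids peptide ids defining the feature order
#' @param undetected encoding of zero amplitudes
#' @return numeric matrix samples x panel peptides
#' @export
feature_transform <- function(matrix, panel_ids,
                              undetected = c("zero", "log1p")) {
  undetected <- match.arg(undetected)
  missing <- setdiff(panel_ids, colnames(matrix))
  if (length(missing) > 0) {
    stop(sprintf("panel peptides absent from matrix: %s",
                 paste(missing, collapse = ", ")))
  }
  a <- matrix[, panel_ids, drop = FALSE]
  if (undetected == "zero") {
    f <- ifelse(a > 0, log2(pmax(a, .Machine$double.xmin)), 0)
  } else {
    f <- log2(a + 1)
  }
  dimnames(f) <- dimnames(a)
  f
}

#' Train the peptide-pattern SVM
#'
#' Fits a soft-margin SVM with radial basis kernel
#' `K(u, v) = exp(-gamma ||u - v||^2)` and cost `C` on the log2 feature
#' table. Features are not standardized: the published kernel parameters
#' are tied to the raw log2 intensity scale. The stored model scores
#' samples by signed distance to the separating hyperplane with positive =
#' case-like, and records its training sensitivity/specificity at score 0.
#'
#' @param features log2 feature matrix from [feature_transform()]
#' @param labels case/control labels
#' @param C soft-margin cost (default: published pattern value)
#' @param gamma RBF kernel width (default: published pattern value)
#' @param seed stored in metadata; the quadratic-programming fit itself is
#'   deterministic
#' @return a `pattern_model`
#' @export
train_pattern <- function(features, labels, C = 1638.4, gamma = 0.000256,
                          seed = 1L) {
  case <- as_case_flag(labels)
  if (!any(case) || all(case)) stop("training labels must contain both classes")
  if (C <= 0 || gamma <= 0) stop("C and gamma must be positive")
  y <- factor(ifelse(case, "case", "control"), levels = c("control", "case"))
  set.seed(seed)
  svm_fit <- e1071::svm(x = features, y = y, type = "C-classification",
                        kernel = "radial", cost = C, gamma = gamma,
                        scale = FALSE)
  raw <- as.numeric(attr(stats::predict(svm_fit, features, decision.values = TRUE),
                         "decision.values"))
  # libsvm's decision sign follows class encounter order; orient so that
  # cases sit on the positive side
  flip <- if (mean(raw[case]) >= mean(raw[!case])) 1 else -1
  score <- flip * raw
  model <- structure(list(svm = svm_fit, panel_ids = colnames(features),
                          C = C, gamma = gamma, seed = seed, sign = flip,
                          train_sens = mean(score[case] > 0),
                          train_spec = mean(score[!case] <= 0),
                          n_train = nrow(features),
                          train_ids = rownames(features)),
                     class = "pattern_model")
  model
}

#' @export
print.pattern_model <- function(x, ...) {
  cat(sprintf("RBF-SVM peptide pattern: %d peptides, C = %g, gamma = %g\n",
              length(x$panel_ids), x$C, x$gamma))
  cat(sprintf("training sens/spec at score 0: %.3f / %.3f (n = %d)\n",
              x$train_sens, x$train_spec, x$n_train))
  invisible(x)
}

#' Score samples with a trained pattern model
#'
#' @param model a `pattern_model`
#' @param features feature matrix whose columns match the model panel
#' @return named numeric vector of classification scores (signed distance
#'   to the hyperplane; positive = case-like)
#' @export
score_samples <- function(model, features) {
  if (!identical(colnames(features), model$panel_ids)) {
    stop("feature columns do not match the model panel (order matters)")
  }
  raw <- as.numeric(attr(stats::predict(model$svm, features, decision.values = TRUE),
                         "decision.values"))
  stats::setNames(model$sign * raw, rownames(features))
}

#' Tune C and gamma by stratified cross-validated grid search
#'
#' Evaluates every lattice point on a stratified k-fold split and returns
#' the pair with the smallest mean misclassification rate; ties go to the
#' smallest C, then the smallest gamma. Folds whose training part is
#' single-class are dropped from the average with a warning.
#'
#' @inheritParams train_pattern
#' @param C_grid,gamma_grid candidate values
#' @param k_folds number of folds (>= 2), stratified by class
#' @return list with `C`, `gamma`, and the full `cv_error` lattice
#' @export
tune_hyperparameters <- function(features, labels, C_grid, gamma_grid,
                                 k_folds = 5L, seed = 1L) {
  case <- as_case_flag(labels)
  if (k_folds < 2) stop("k_folds must be >= 2")
  if (length(C_grid) == 0 || length(gamma_grid) == 0) stop("grids must be non-empty")
  set.seed(seed)
  fold <- integer(length(case))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(case == cls)
    fold[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
  }
  grid <- expand.grid(C = sort(C_grid), gamma = sort(gamma_grid))
  grid$cv_error <- NA_real_
  for (g in seq_len(nrow(grid))) {
    errs <- rep(NA_real_, k_folds)
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      if (length(unique(case[tr])) < 2) next
      m <- train_pattern(features[tr, , drop = FALSE], case[tr],
                         C = grid$C[g], gamma = grid$gamma[g], seed = seed)
      sc <- score_samples(m, features[!tr, , drop = FALSE])
      errs[f] <- mean((sc > 0) != case[!tr])
    }
    if (anyNA(errs)) warning("single-class training fold dropped from CV average")
    grid$cv_error[g] <- mean(errs, na.rm = TRUE)
  }
  best <- grid[order(grid$cv_error, grid$C, grid$gamma), ][1, ]
  list(C = best$C, gamma = best$gamma, cv_error = grid)
}

#' Composite-score weights
#'
#' Container for the linear composite combining the peptide-pattern score,
#' a coronary-artery-disease pattern score, and age. Defaults are the
#' published composite: `0.2 * pattern + 2.6 * cad + 0.15 * age`, with
#' classification threshold 10.256.
#' @param w_pattern,w_cad,w_age linear weights
#' @param threshold classification cut-off on the composite scale
#' @export
composite_weights <- function(w_pattern = 0.2, w_cad = 2.6, w_age = 0.15,
                              threshold = 10.256) {
  stopifnot(is.finite(w_pattern), is.finite(w_cad), is.finite(w_age))
  structure(list(w_pattern = w_pattern, w_cad = w_cad, w_age = w_age,
                 threshold = threshold),
            class = "composite_weights")
}

#' Composite risk score
#'
#' @param pattern_score peptide-pattern classification score
#' @param cad_score coronary-artery-disease pattern score (input covariate)
#' @param age_years age in years
#' @param weights a [composite_weights()]
#' @return numeric composite score(s)
#' @export
composite_score <- function(pattern_score, cad_score, age_years,
                            weights = composite_weights()) {
  stopifnot(all(is.finite(pattern_score)), all(is.finite(cad_score)),
            all(is.finite(age_years)))
  weights$w_pattern * pattern_score + weights$w_cad * cad_score +
    weights$w_age * age_years
}

# ridge-penalized logistic IRLS fallback for separated data
ridge_logistic <- function(X, y, lambda = 1e-4, tol = 1e-10, maxit = 100) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0  # intercept unpenalized
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(new - beta)) < tol) { beta <- drop(new); break }
    beta <- drop(new)
  }
  beta
}

#' Fit composite weights by logistic regression
#'
#' Regresses case/control status on pattern score, CAD pattern score, and
#' age (iteratively reweighted least squares via `glm`); the slope
#' coefficients become the composite weights and Wald p-values are reported
#' per covariate. Perfect separation triggers a ridge-penalized refit
#' (lambda = 1e-4) with a warning.
#'
#' @param pattern_scores,cad_scores,ages covariate vectors
#' @param labels case/control labels (>= 10 samples per class)
#' @return list with `weights` (a [composite_weights()] with threshold NA),
#'   `coefficients`, `p_values`, and `separation` flag
#' @export
fit_composite_weights <- function(pattern_scores, cad_scores, ages, labels) {
  case <- as_case_flag(labels)
  if (sum(case) < 10 || sum(!case) < 10) stop("need >= 10 samples per class")
  df <- data.frame(y = as.integer(case), pattern = pattern_scores,
                   cad = cad_scores, age = ages)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ pattern + cad + age, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated) {
    warning("perfect separation detected; ridge-penalized refit (lambda = 1e-4)")
    X <- cbind(1, df$pattern, df$cad, df$age)
    beta <- ridge_logistic(X, df$y)
    coefs <- stats::setNames(beta, c("(Intercept)", "pattern", "cad", "age"))
    pvals <- stats::setNames(rep(NA_real_, 3), c("pattern", "cad", "age"))
  } else {
    coefs <- stats::coef(fit)
    sm <- summary(fit)$coefficients
    pvals <- stats::setNames(sm[-1, "Pr(>|z|)"], rownames(sm)[-1])
  }
  list(weights = composite_weights(coefs[["pattern"]], coefs[["cad"]],
                                   coefs[["age"]], threshold = NA_real_),
       coefficients = coefs, p_values = pvals, separation = separated)
}
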