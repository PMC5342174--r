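# Independent brute-force oracles and small fixture builders used across
# the suite. Each oracle is written from the definition, not from the
# implementation it checks.

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# assignments of the pooled ranks to group 1.
enumerate_wilcoxon_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  w_all <- apply(combos, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  min(1, mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9))
}

# Harrell's c by an explicit double loop over ordered pairs.
brute_force_c <- function(scores, time, event) {
  n <- length(scores)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      early <- if (time[i] < time[j]) i else j
      late <- if (time[i] < time[j]) j else i
      if (event[early] != 1) next
      den <- den + 1
      if (scores[early] > scores[late]) num <- num + 1
      else if (scores[early] == scores[late]) num <- num + 0.5
    }
  }
  num / den
}

# Youden scan over a dense set of candidate thresholds (all observed
# values nudged either way), computed with table arithmetic.
brute_force_youden_J <- function(scores, labels) {
  case <- labels == 1 | labels == TRUE
  eps <- min(diff(sort(unique(scores)))) / 4
  if (!is.finite(eps)) eps <- 1e-9
  cand <- sort(unique(c(scores - eps, scores + eps)))
  best <- -Inf
  for (t in cand) {
    sens <- sum(scores[case] > t) / sum(case)
    spec <- sum(scores[!case] <= t) / sum(!case)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Hand step-up BH: adj_(i) = min_{j >= i} m * p_(j) / j, back in input order.
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Small, fast simulation configuration used by many tests.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_cases = 20L, n_controls = 20L, n_peptides = 60L,
         n_true_biomarkers = 8L, n_housekeeping = 8L,
         log2_effect_mean = 2, log2_effect_sd = 0.2,
         biomarker_detect_freq = 1.0, seed = 42L),
    list(...))
  do.call(sim_config, args)
}

# Deterministic toy two-class feature set: two Gaussian blobs.
toy_blobs <- function(n = 20, sep = 10, sd = 0.5, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * 2, 0, sd), ncol = 2),
             matrix(rnorm(n * 2, sep, sd), ncol = 2))
  colnames(x) <- c("f1", "f2")
  rownames(x) <- sprintf("s%03d", seq_len(2 * n))
  list(x = x, y = rep(c(FALSE, TRUE), each = n))
}
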