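# Independent oracles used across the suite. These deliberately use naive,
# readable algorithms (double loops, dense enumeration, numerical
# integration) so they stay independent of the implementation they check.

# Naive double-loop evaluation of the cross-validated distance:
# d_ij = sum over ordered run pairs (l, m), l != m, of
#        (u_i^m - u_j^m)' (u_i^l - u_j^l), divided by M(M-1).
naive_crossnobis <- function(runs) {
  M <- length(runs)
  K <- nrow(runs[[1]])
  d <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    acc <- 0
    for (l in seq_len(M)) for (m in seq_len(M)) {
      if (l == m) next
      acc <- acc + sum((runs[[m]][i, ] - runs[[m]][j, ]) *
                         (runs[[l]][i, ] - runs[[l]][j, ]))
    }
    d[i, j] <- acc / (M * (M - 1))
  }
  d
}

# One-tailed upper p for a t statistic by numerical integration of the t
# density (independent of pt()).
p_upper_t_oracle <- function(t, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  stats::integrate(dens, t, Inf, rel.tol = 1e-10)$value
}

# Brute-force pair filter over all C(n,2) unordered pairs.
brute_force_pairs <- function(conditions, category = "ignore",
                              domain = "ignore", quadrant = "ignore",
                              restrict = list()) {
  match1 <- function(pred, a, b) {
    if (pred == "ignore") return(TRUE)
    if (is.na(a) || is.na(b)) return(FALSE)
    if (pred == "same") a == b else a != b
  }
  out <- list()
  n <- nrow(conditions)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- match1(category, conditions$category[i], conditions$category[j]) &&
      match1(domain, conditions$domain[i], conditions$domain[j]) &&
      match1(quadrant, conditions$quadrant[i], conditions$quadrant[j])
    for (f in names(restrict)) {
      ok <- ok && conditions[[f]][i] %in% restrict[[f]] &&
        conditions[[f]][j] %in% restrict[[f]]
    }
    if (ok) out[[length(out) + 1L]] <- c(i, j)
  }
  if (length(out)) do.call(rbind, out) else matrix(0L, 0, 2)
}

# Ordered successor-pair counts of a sequence over all n^2 pairs
# (including self-successions).
pair_counts <- function(s, n) {
  lv <- as.vector(outer(seq_len(n), seq_len(n),
                        function(a, b) paste(a, b)))
  table(factor(paste(s[-length(s)], s[-1]), levels = lv))
}

# Tiny two-condition test conditions table.
toy_conditions <- function(ids = c("a", "b")) {
  data.frame(condition_id = ids, item_id = ids,
             label = ids, category = "x",
             quadrant = NA_character_, domain = "imagery",
             experiment = 0L, stringsAsFactors = FALSE)
}

# Minimal carry-over timeline over arbitrary conditions (2 s trials with a
# 2 s gap), for pipeline tests that do not need the full experiment
# layouts.
toy_timeline <- function(conditions, n_trials, seed = 1L) {
  s <- carryover_sequence(nrow(conditions), n_trials, seed = seed)
  tl <- data.frame(
    onset = (seq_len(n_trials) - 1) * 4,
    duration = 2,
    kind = "experimental",
    condition_id = conditions$condition_id[s],
    item_id = conditions$item_id[s],
    label = conditions$label[s],
    category = conditions$category[s],
    domain = conditions$domain[s],
    quadrant = conditions$quadrant[s],
    stringsAsFactors = FALSE)
  attr(tl, "conditions") <- conditions
  class(tl) <- c("trial_timeline", "data.frame")
  tl
}
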