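# Independent brute-force oracles used across the suite. These re-derive
# the statistics from first principles and must stay free of any package
# internals beyond plain data structures.

# Two-group log-rank by direct O/E/V tabulation over risk sets.
oracle_logrank2 <- function(time, event, group) {
  group <- as.integer(factor(group))
  stopifnot(length(unique(group)) == 2)
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    d_j <- sum(event == 1 & time == t)
    n1j <- sum(at_risk & group == 1)
    d1j <- sum(event == 1 & time == t & group == 1)
    O <- O + d1j
    E <- E + d_j * n1j / n_j
    if (n_j > 1)
      V <- V + d_j * (n1j / n_j) * (1 - n1j / n_j) * (n_j - d_j) / (n_j - 1)
  }
  list(statistic = (O - E)^2 / V, O = O, E = E, V = V)
}

# Kaplan-Meier product-limit estimate by hand.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n_j <- sum(time >= ts[i])
    d_j <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d_j / n_j)
    surv[i] <- s
  }
  list(event_times = ts, survival = surv)
}

# Upper-tail hypergeometric probability by direct summation of the
# enumeration formula sum_i C(K,i) C(N-K,n-i) / C(N,n) for i >= k.
oracle_hypergeom <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# k-TSP delta/gamma for one gene pair by explicit frequency counting.
oracle_tsp_pair <- function(xi, xj, in1) {
  less <- ifelse(xi < xj, 1, ifelse(xi == xj, 0.5, 0))
  delta <- abs(mean(less[in1]) - mean(less[!in1]))
  delta
}

# Per-sample within-matrix ranks for the gamma tie-break oracle.
oracle_tsp_gamma <- function(X, i, j, in1) {
  R <- apply(X, 2, rank)
  rd <- R[i, ] - R[j, ]
  abs(mean(rd[in1]) - mean(rd[!in1]))
}

# Simple exponential survival sampler for null/planted scenarios.
sim_surv <- function(n, hazard, censor_rate = 0.008, horizon = 240) {
  te <- stats::rexp(n, hazard)
  tc <- pmin(stats::rexp(n, censor_rate), horizon)
  list(time = pmin(te, tc), event = as.integer(te <= tc))
}

# Tiny deterministic expression fixture: 3 genes x (2 ref + 3 tumor).
toy_expression <- function() {
  vals <- matrix(c(1, 2, 4, 6, 8,
                   5, 7, 6, 6, 6,
                   10, 14, 12, 2, 30),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("GA", "GB", "GC"),
                                 c("R1", "R2", "T1", "T2", "T3")))
  expression_matrix(vals, c(TRUE, TRUE, FALSE, FALSE, FALSE))
}

toy_clinical <- function(ids = c("T1", "T2", "T3"),
                         time = c(10, 20, 30), event = c(1, 1, 0)) {
  clinical_table(data.frame(sample_id = ids, time_months = time,
                            event = event, stringsAsFactors = FALSE))
}
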