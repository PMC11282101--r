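# Shared fixtures: small synthetic cohorts and independent oracle helpers.

small_config <- function(seed = 1, n_samples = 60, n_genes = 400,
                         effect = 2, ...) {
  cohort_config(n_samples = n_samples, n_genes = n_genes,
                program_genes_per_subtype = 10,
                program_down_genes_per_subtype = 10,
                program_log2_effect = effect, seed = seed, ...)
}

small_cohort <- function(seed = 1, ...) simulate_cohort(small_config(seed, ...))

rand_expr <- function(g, n, seed = 1, state = "LOG2_QNORM") {
  set.seed(seed)
  m <- matrix(abs(rnorm(g * n, 6, 2)), g, n,
              dimnames = list(sprintf("g%03d", 1:g), sprintf("s%03d", 1:n)))
  expression_matrix(m, state)
}

# Adjusted Rand index between two partitions.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Independent step-by-step ssGSEA walk oracle: plain loops, straight from
# the definition (no shared code with the package implementation).
ssgsea_oracle <- function(values, set_idx, tau) {
  n <- length(values)
  rk <- rank(values, ties.method = "average")
  ord <- order(-values, seq_len(n))
  p_in <- 0; p_out <- 0; es <- 0
  w_tot <- sum(rk[set_idx]^tau)
  for (pos in seq_len(n)) {
    gene <- ord[pos]
    if (gene %in% set_idx) p_in <- p_in + rk[gene]^tau / w_tot
    else p_out <- p_out + 1 / (n - length(set_idx))
    es <- es + (p_in - p_out)
  }
  as.numeric(es)
}

# Exhaustive BH step-up oracle for small n.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    vals <- vapply(i:n, function(j) min(1, n * p[o[j]] / j), 0)
    q[o[i]] <- min(vals)
  }
  q
}

# Log-rank oracle: loop over distinct event times accumulating O-E and the
# hypergeometric variance for group 1.
logrank_oracle <- function(time, event, group) {
  group <- as.integer(factor(group))
  stopifnot(max(group) == 2)
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n_tot
    if (n_tot > 1)
      v <- v + d * (n1 / n_tot) * (1 - n1 / n_tot) * (n_tot - d) / (n_tot - 1)
  }
  (o_minus_e)^2 / v
}
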