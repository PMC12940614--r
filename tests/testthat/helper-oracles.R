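# Independent oracles used across the suite. These are deliberately naive
# re-implementations (loops, enumeration, grid search) kept separate from the
# package's code paths.

# brute-force running-sum enrichment score for one sample
oracle_es <- function(z, inset, tau = 1) {
  stopifnot(length(z) == length(inset))
  G <- length(z)
  m <- sum(inset)
  if (m == G) return(1)
  ord <- order(z, decreasing = TRUE, method = "radix")
  rs <- 0
  path <- numeric(G)
  w_in <- abs(z)^tau
  tot <- sum(w_in[inset])
  for (pos in seq_len(G)) {
    g <- ord[pos]
    rs <- rs + if (inset[g]) {
      if (tot > 0) w_in[g] / tot else 1 / m
    } else -1 / (G - m)
    path[pos] <- rs
  }
  max(path, 0) + min(path, 0)
}

# Breslow-ties Cox partial log-likelihood for a single covariate
oracle_cox_loglik <- function(beta, score, time, event) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + beta * sum(score[d]) -
      length(d) * log(sum(exp(beta * score[risk])))
  }
  ll
}

# exhaustive Mann-Whitney pair count
oracle_auc <- function(score, pos) {
  x <- score[pos]; y <- score[!pos]
  tot <- 0
  for (xi in x) for (yj in y)
    tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  tot / (length(x) * length(y))
}

# small deterministic expression fixture (genes x samples, log2 scale)
toy_expression <- function(n_genes = 8, n_samples = 5, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(round(runif(n_genes * n_samples, 0, 8), 3), nrow = n_genes,
                dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                                sprintf("S%02d", seq_len(n_samples))))
    m
  })
}

# standard small cohort simulation used by several tests
toy_cohorts <- function(n_cohorts = 3, n = 40, gamma = 2, delta = -0.5,
                        n_genes = 60, seed = 1) {
  truth <- truth_set(sprintf("TLS%02d", 1:5),
                     activity_effect_response = gamma,
                     activity_effect_hazard = delta)
  simulate_cohorts(n_cohorts, n, n_genes, truth, seed = seed)
}
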