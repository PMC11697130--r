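# Shared fixtures and independent oracles, built in code at test time.

# k=1 nearest-neighbour graph over n collinear points at x = 0, 1, ..., n-1
line_graph <- function(n = 5, k = 1) {
  knn_graph(data.frame(x = seq_len(n) - 1, y = 0), k = k)
}

# sticks whose first two weights are ~(p1, 1 - p1) with a ~1e-12 tail,
# so the label space is effectively binary for kernel-vs-oracle checks
binary_sticks <- function(p1 = 0.6, alpha = 1) {
  new_sticks(c(p1, 1 - 2.5e-12), alpha = alpha)
}

# brute-force ARI oracle: classify all n(n-1)/2 cell pairs as together /
# apart in each partition and apply the chance-corrected Rand formula
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else if (!sa && sb) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  np <- n11 + n10 + n01 + n00
  expected <- (n11 + n10) * (n11 + n01) / np
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_index == expected) return(0)
  (n11 - expected) / (max_index - expected)
}

# independent transcription of the exchange acceptance log-ratio, written
# directly from the three printed factors with its own truncated-normal
# density, to cross-check double_mh_accept
log_r_oracle <- function(labels, xi, beta, labels_star, xi_star, beta_star,
                         graph, hyper) {
  tn <- function(x, m, s2, a, b) {
    dnorm(x, m, sqrt(s2)) / (pnorm(b, m, sqrt(s2)) - pnorm(a, m, sqrt(s2)))
  }
  pi_of <- function(xi) xi * c(1, cumprod(1 - xi)[-length(xi)])
  pi <- pi_of(xi)
  pi_s <- pi_of(xi_star)
  R0 <- hyper$R0
  S <- function(C) directed_agreement(C, graph)
  f1 <- prod((1 - xi_star[1:R0])^(hyper$alpha - 1)) /
        prod((1 - xi[1:R0])^(hyper$alpha - 1)) *
        tn(beta_star, hyper$a_beta, hyper$tau2_beta, 0, Inf) /
        tn(beta, hyper$a_beta, hyper$tau2_beta, 0, Inf)
  f2 <- prod(tn(xi[1:R0], xi_star[1:R0], hyper$tau2_0, 0, 1)) /
        prod(tn(xi_star[1:R0], xi[1:R0], hyper$tau2_0, 0, 1)) *
        tn(beta, beta_star, hyper$tau2_1, 0, Inf) /
        tn(beta_star, beta, hyper$tau2_1, 0, Inf)
  log_f3 <- sum(log(pi_s[labels])) + beta_star * S(labels) +
            sum(log(pi[labels_star])) + beta * S(labels_star) -
            sum(log(pi[labels])) - beta * S(labels) -
            sum(log(pi_s[labels_star])) - beta_star * S(labels_star)
  log(f1) + log(f2) + log_f3
}

# empirical distribution of a chain of label configurations (n x S matrix)
# over the L^n enumeration order used by exact_potts_distribution
empirical_config_dist <- function(trace, L) {
  idx <- spotts:::potts_config_index(trace, L)
  tabulate(idx, nbins = L^nrow(trace)) / ncol(trace)
}

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# reference synthetic dataset for the recovery studies (study conditions:
# 500 cells, 4 types, beta 1, 5-sigma separation, H = 3, k = 6)
reference_sim <- function(seed = 7) {
  simulate_st_data(sim_config(n_cells = 500, K_true = 4, beta_gen = 1,
                              mean_separation = 5, H_sim = 3, k_sim = 6,
                              seed = seed))
}
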