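#' Unnormalised log-score of the nonparametric Potts model
#'
#' The log of the numerator of the Potts joint over cell labels,
#' \eqn{\sum_i \log \pi_{C_i} + \beta \sum_i \sum_{j \in Nei_k(i)} I(C_i = C_j)},
#' with the intractable normalising constant omitted.
#'
#' @param labels positive-integer label vector.
#' @param graph a [knn_graph()].
#' @param beta spatial interaction strength (> 0, or 0 for the independent
#'   product measure).
#' @param weights cluster weights: either a numeric probability prefix
#'   \eqn{(\pi_1, ..., \pi_L)} or a [new_sticks()] object. Every label used
#'   must be instantiated.
#' @return A single real number.
#' @export
potts_log_score <- function(labels, graph, beta, weights) {
  pi <- if (inherits(weights, "sticks")) stick_weights(weights) else weights
  labels <- as.integer(labels)
  if (max(labels) > length(pi)) {
    stop("label ", max(labels), " exceeds the ", length(pi),
         " instantiated cluster weights")
  }
  if (min(labels) < 1) stop("labels must be positive integers")
  sum(log(pi[labels])) + beta * directed_agreement(labels, graph)
}

#' Gaussian emission log-likelihood of one cell
#'
#' Log-density of a cell's PC vector under cluster `l`'s diagonal Gaussian
#' emission model, \eqn{\sum_h \log N(Y_{hi} | \eta_{hl}, \sigma_h^2)}.
#'
#' @param y length-H numeric vector of PC scores for one cell.
#' @param l cluster label (column of `eta`).
#' @param eta H x L matrix of per-cluster, per-PC means.
#' @param sigma2 length-H vector of per-PC variances, all positive.
#' @return A single real number.
#' @export
emission_loglik_cell <- function(y, l, eta, sigma2) {
  if (any(sigma2 <= 0)) stop("all variances sigma2 must be positive")
  if (l < 1 || l > ncol(eta)) stop("cluster ", l, " has no emission mean")
  sum(dnorm(y, mean = eta[, l], sd = sqrt(sigma2), log = TRUE))
}

#' Exact truncated Potts distribution by enumeration
#'
#' Testing oracle for small instances: enumerates all `L^n` label vectors of
#' the Potts model truncated to `L` labels (weights renormalised over those
#' labels) and returns exact probabilities. Intended for `L^n <= 1e6`.
#'
#' @inheritParams potts_log_score
#' @param pi length-L weight vector (renormalised internally).
#' @return A list: `labels` (N x n integer matrix of configurations, one per
#'   row), `prob` (length-N probabilities summing to 1), `log_z` (log
#'   normalising constant of the renormalised model).
#' @export
exact_potts_distribution <- function(graph, beta, pi) {
  stopifnot(inherits(graph, "knn_graph"), beta >= 0, all(pi > 0))
  L <- length(pi)
  n <- graph$n
  if (L^n > 1e6) stop("instance too large to enumerate (L^n > 1e6)")
  pi <- pi / sum(pi)
  logp <- enumerate_potts_scores_cpp(graph$nb, beta, pi)
  m <- max(logp)
  log_z <- m + log(sum(exp(logp - m)))
  # configuration index: cell 1 is the least significant base-L digit
  idx <- 0:(L^n - 1)
  labels <- matrix(0L, length(idx), n)
  r <- idx
  for (i in seq_len(n)) {
    labels[, i] <- r %% L + 1L
    r <- r %/% L
  }
  list(labels = labels, prob = exp(logp - log_z), log_z = log_z)
}

# map an n-vector (or n x S matrix) of labels to 1-based enumeration indices
potts_config_index <- function(labels, L) {
  if (is.matrix(labels)) {
    pow <- L^(seq_len(nrow(labels)) - 1)
    as.integer(colSums((labels - 1) * pow) + 1)
  } else {
    pow <- L^(seq_along(labels) - 1)
    as.integer(sum((labels - 1) * pow) + 1)
  }
}

# --- truncated normal helpers (density and sampler on (a, b)) ---------------

dtnorm <- function(x, mean, sd, a = 0, b = Inf, log = FALSE) {
  lz <- log(pnorm(b, mean, sd) - pnorm(a, mean, sd))
  ld <- dnorm(x, mean, sd, log = TRUE) - lz
  ld[x <= a | x >= b] <- -Inf
  if (log) ld else exp(ld)
}

rtnorm <- function(n, mean, sd, a = 0, b = Inf) {
  pa <- pnorm(a, mean, sd)
  pb <- pnorm(b, mean, sd)
  q <- qnorm(pa + runif(n) * (pb - pa), mean, sd)
  pmin(pmax(q, a + 1e-12), b - if (is.finite(b)) 1e-12 else 0)
}
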