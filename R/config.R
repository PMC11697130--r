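#' Model hyperparameters
#'
#' Weakly informative defaults for the priors and the double-MH proposal.
#'
#' @param a_beta,tau2_beta location and scale of the truncated-normal prior
#'   `N(a_beta, tau2_beta) I(beta > 0)` on the spatial interaction strength.
#' @param a_eta,b2_eta mean and variance of the normal prior on each
#'   per-cluster, per-PC emission mean.
#' @param kappa,tau shape and scale of the inverse-gamma prior on each
#'   per-PC emission variance.
#' @param alpha stick-breaking concentration parameter.
#' @param R0 proposal truncation depth: the number of leading sticks given a
#'   random-walk proposal (sticks beyond R0 are refreshed from the prior).
#' @param tau2_0,tau2_1 random-walk proposal variances for the sticks and
#'   for beta.
#' @return An object of class `"potts_hyper"`.
#' @export
potts_hyperparams <- function(a_beta = 1, tau2_beta = 1,
                              a_eta = 0, b2_eta = 10,
                              kappa = 2, tau = 1,
                              alpha = 1, R0 = 50,
                              tau2_0 = 0.01, tau2_1 = 0.01) {
  h <- list(a_beta = a_beta, tau2_beta = tau2_beta, a_eta = a_eta,
            b2_eta = b2_eta, kappa = kappa, tau = tau, alpha = alpha,
            R0 = as.integer(R0), tau2_0 = tau2_0, tau2_1 = tau2_1)
  stopifnot(h$tau2_beta > 0, h$b2_eta > 0, h$kappa > 0, h$tau > 0,
            h$alpha > 0, h$R0 >= 1, h$tau2_0 > 0, h$tau2_1 > 0)
  structure(h, class = "potts_hyper")
}

#' MCMC run configuration
#'
#' @param n_iter total number of iterations (default 6000).
#' @param burn_in number of leading iterations discarded (default 3000).
#' @param seed RNG seed for the whole run; chains are bit-reproducible
#'   given `(config, seed)`.
#' @param init_k number of clusters used by the k-means initialisation.
#'   This only seeds the chain; the stick-breaking prior lets the occupied
#'   cluster count move freely afterwards.
#' @param thin storage stride for post-burn-in samples.
#' @param store_labels keep the full label vector of every stored iteration
#'   (needed for the posterior point estimate).
#' @param verbose print progress every `report_every` iterations (0 = quiet).
#' @param report_every progress interval in iterations.
#' @param validate check slice/stick invariants at every iteration and
#'   record the worst case (cheap; used by the self-check suite).
#' @return An object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_iter = 6000, burn_in = 3000, seed = 1,
                        init_k = 5, thin = 1, store_labels = TRUE,
                        verbose = FALSE, report_every = 500,
                        validate = TRUE) {
  stopifnot(burn_in < n_iter, init_k >= 1, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 seed = as.integer(seed), init_k = as.integer(init_k),
                 thin = as.integer(thin), store_labels = store_labels,
                 verbose = verbose, report_every = as.integer(report_every),
                 validate = validate),
            class = "mcmc_config")
}
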