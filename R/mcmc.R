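#' Initialise the sampler state
#'
#' Labels are seeded by k-means on the PC scores with `init_k` centres;
#' emission means are set to the cluster means, per-PC variances to pooled
#' within-cluster variances (floored at 1e-6), beta to its prior location,
#' and sticks so the leading weights match the empirical cluster
#' frequencies (scaled by 0.99, leaving 1% tail mass for unoccupied
#' clusters) with prior draws extending the prefix to at least `R0`.
#' `init_k` only seeds the chain; the nonparametric prior moves the
#' occupied-cluster count freely afterwards.
#'
#' @param Y H x n matrix of PC scores (a `"pc_matrix"` or plain matrix).
#' @param graph a [knn_graph()] over the same cells.
#' @param hyper a [potts_hyperparams()].
#' @param config an [mcmc_config()]; only `init_k` is used here.
#' @return A `"potts_state"` list with elements `C`, `u`, `beta`, `sticks`,
#'   `eta`, `sigma2`. Uses the R RNG (seed beforehand for reproducibility).
#' @export
initialize_state <- function(Y, graph, hyper = potts_hyperparams(),
                             config = mcmc_config()) {
  Y <- as.matrix(Y)
  n <- ncol(Y)
  stopifnot(inherits(graph, "knn_graph"), graph$n == n)
  K0 <- config$init_k
  if (K0 > n) stop("init_k = ", K0, " exceeds the number of cells ", n)
  if (K0 == 1) {
    C <- rep(1L, n)
    centers <- matrix(rowMeans(Y), nrow = 1)
  } else {
    km <- kmeans(t(Y), centers = K0, nstart = 5, iter.max = 50)
    C <- as.integer(km$cluster)
    centers <- km$centers
  }
  eta <- t(centers) # H x K0
  sigma2 <- pmax(rowMeans((Y - eta[, C, drop = FALSE])^2), 1e-6)
  sticks <- sticks_from_frequencies(tabulate(C, nbins = K0), hyper$alpha,
                                    tail_reserve = 0.01, min_len = hyper$R0)
  eta <- grow_eta(eta, length(sticks$xi), hyper)
  pi <- stick_weights(sticks)
  u <- runif(n, 0, pi[C])
  structure(list(C = C, u = u, beta = hyper$a_beta, sticks = sticks,
                 eta = eta, sigma2 = sigma2),
            class = "potts_state")
}

# append prior-drawn emission-mean columns for newly instantiated clusters
grow_eta <- function(eta, L, hyper) {
  H <- nrow(eta)
  extra <- L - ncol(eta)
  if (extra > 0) {
    eta <- cbind(eta, matrix(rnorm(H * extra, hyper$a_eta,
                                   sqrt(hyper$b2_eta)), H, extra))
  }
  eta
}

#' Sample the slice variables
#'
#' Step (b): each auxiliary slice variable is redrawn uniformly,
#' `u_i ~ Unif(0, pi[C_i])`, restoring `u_i <= pi[C_i]` by construction.
#'
#' @param labels current label vector.
#' @param sticks a [new_sticks()] object instantiated at least to
#'   `max(labels)`.
#' @return Numeric vector `u` of slice variables.
#' @export
sample_u <- function(labels, sticks) {
  pi <- stick_weights(sticks)
  if (max(labels) > length(pi)) stop("labels exceed instantiated sticks")
  runif(length(labels), 0, pi[labels])
}

#' Sequential slice-restricted label update
#'
#' Step (c): cells are scanned in index order and each label is redrawn
#' from the finite candidate set `{l : pi_l >= u_i}` with probability
#' proportional to `exp(beta * a_il)` times the Gaussian emission
#' likelihood, where `a_il` counts matching labels over the interaction
#' neighbourhood of cell i (out- and in-neighbours of the directed kNN
#' relation — every term of the Potts double sum that involves `C_i`).
#' Neighbour labels reflect already-updated cells within the sweep.
#'
#' @inheritParams sample_u
#' @param u slice variables from [sample_u()]; `sticks` must already be
#'   extended so the tail mass is below `min(u)` (see [extend_sticks()]).
#' @param Y H x n matrix of PC scores.
#' @param graph a [knn_graph()].
#' @param beta spatial interaction strength.
#' @param eta H x L emission means covering all instantiated sticks.
#' @param sigma2 length-H emission variances.
#' @return Updated integer label vector.
#' @export
update_labels <- function(labels, u, Y, graph, beta, sticks, eta, sigma2) {
  pi <- stick_weights(sticks)
  if (stick_tail_mass(sticks) >= min(u)) {
    stop("sticks not extended below min(u); call extend_sticks first")
  }
  if (ncol(eta) < length(pi)) stop("eta lacks columns for instantiated sticks")
  out <- label_sweep_cpp(as.integer(labels), as.matrix(Y), eta, sigma2,
                         beta, pi, u, graph$nb, graph$in_ptr, graph$in_idx,
                         n_sweeps = 1L, resample_u = FALSE,
                         store_trace = FALSE)
  out$C
}

#' Conjugate update of the emission means
#'
#' Step (d): for every instantiated cluster l and PC h,
#' `eta_hl ~ N(a_tilde, b2_tilde)` with
#' `a_tilde = (sum_{i: C_i = l} Y_hi / sigma2_h + a_eta / b2_eta) /
#' (m_l / sigma2_h + 1 / b2_eta)` and
#' `b2_tilde = 1 / (m_l / sigma2_h + 1 / b2_eta)`; empty clusters
#' (`m_l = 0`) reduce exactly to fresh prior draws.
#'
#' @inheritParams update_labels
#' @param L number of instantiated clusters (columns to update).
#' @param hyper a [potts_hyperparams()].
#' @return New H x L matrix of emission means.
#' @export
update_eta <- function(labels, Y, sigma2, L, hyper) {
  Y <- as.matrix(Y)
  H <- nrow(Y)
  m <- tabulate(labels, nbins = L)
  S <- matrix(0, H, L)
  sums <- rowsum(t(Y), group = labels) # occupied clusters, sorted label order
  S[, sort(unique(labels))] <- t(sums)
  prec <- outer(1 / sigma2, m) + 1 / hyper$b2_eta
  mean_post <- (S / sigma2 + hyper$a_eta / hyper$b2_eta) / prec
  mean_post + matrix(rnorm(H * L), H, L) / sqrt(prec)
}

#' Conjugate update of the per-PC variances
#'
#' Step (e): each `sigma2_h` is drawn from
#' inv-Gamma(`kappa + n/2`, `tau + 0.5 * sum_i (Y_hi - eta_{h C_i})^2`),
#' independently across PCs.
#'
#' @inheritParams update_eta
#' @param eta current H x L emission means.
#' @return New length-H variance vector.
#' @export
update_sigma2 <- function(labels, Y, eta, hyper) {
  Y <- as.matrix(Y)
  n <- ncol(Y)
  ss <- rowSums((Y - eta[, labels, drop = FALSE])^2)
  1 / rgamma(nrow(Y), shape = hyper$kappa + n / 2, rate = hyper$tau + ss / 2)
}

#' Random-walk proposal for the sticks and the interaction strength
#'
#' Substep (a1): the leading `R0` sticks receive truncated-normal
#' random-walk proposals on (0, 1) with variance `tau2_0`; instantiated
#' sticks beyond `R0` are refreshed from the Beta(1, alpha) prior; beta
#' receives a truncated-normal random walk on (0, Inf) with variance
#' `tau2_1`.
#'
#' @inheritParams sample_u
#' @param beta current interaction strength.
#' @param hyper a [potts_hyperparams()].
#' @return List with `xi_star` (same length as the instantiated prefix) and
#'   `beta_star`.
#' @export
propose_beta_xi <- function(sticks, beta, hyper) {
  xi <- sticks$xi
  L <- length(xi)
  R0 <- min(hyper$R0, L)
  xi_star <- xi
  xi_star[seq_len(R0)] <- rtnorm(R0, xi[seq_len(R0)], sqrt(hyper$tau2_0),
                                 0, 1)
  if (L > R0) {
    xi_star[(R0 + 1):L] <- clamp_xi(rbeta(L - R0, 1, hyper$alpha))
  }
  list(xi_star = clamp_xi(xi_star),
       beta_star = rtnorm(1, beta, sqrt(hyper$tau2_1), 0, Inf))
}

#' Auxiliary-label sweep of the exchange update
#'
#' Substep (a2): starting from the current labels, one sequential sweep
#' draws each auxiliary label with probability
#' `p*_il = pi*_l exp(beta* a_il) / D_i` for `l <= R_i` and `pi*_l / D_i`
#' beyond, where `R_i` is the largest label in the interaction
#' neighbourhood of cell i, `a_il` the matching-label count over that
#' neighbourhood, and `D_i = 1 + sum_{l <= R_i} pi*_l (exp(beta* a_il) - 1)`
#' (the probabilities sum to one because the full stick weights do). Labels
#' are drawn by inversion of the CDF; draws falling in the un-instantiated
#' tail extend the sticks with Beta(1, alpha) prior draws.
#'
#' @param labels current label vector (the sweep starts here).
#' @param xi_star proposal stick variables (numeric vector).
#' @param beta_star proposal interaction strength.
#' @param graph a [knn_graph()].
#' @param alpha stick-breaking concentration, for tail extension.
#' @param n_sweeps number of sweeps (1 inside the sampler; more for kernel
#'   diagnostics).
#' @param store_trace keep the label vector after every sweep.
#' @return List with `labels_star`, the possibly-extended `xi_star`, and
#'   optionally `trace` (n x n_sweeps matrix).
#' @export
auxiliary_gibbs_sweep <- function(labels, xi_star, beta_star, graph,
                                  alpha = 1, n_sweeps = 1,
                                  store_trace = FALSE) {
  if (max(labels) > length(xi_star)) {
    stop("sticks must be instantiated at least to max(labels)")
  }
  out <- aux_sweep_cpp(as.integer(labels), graph$nb, graph$in_ptr,
                       graph$in_idx, beta_star, as.numeric(xi_star), alpha,
                       as.integer(n_sweeps), store_trace)
  res <- list(labels_star = out$C, xi_star = out$xi)
  if (store_trace) res$trace <- out$trace
  res
}

#' Exchange (double Metropolis-Hastings) accept/reject
#'
#' Substep (a3): the acceptance ratio is the product of (i) the prior ratio
#' of the proposed over current sticks (through `(1 - xi)^(alpha - 1)` for
#' the leading `R0` sticks) and beta, (ii) the reversed proposal ratio, and
#' (iii) the exchange ratio
#' `ptilde(C | theta*) ptilde(C* | theta) / [ptilde(C | theta)
#' ptilde(C* | theta*)]` of unnormalised Potts scores with the parameter
#' roles swapped, which cancels the intractable normalising constant.
#'
#' @param labels,xi,beta current labels, stick variables and interaction
#'   strength.
#' @param labels_star auxiliary labels from [auxiliary_gibbs_sweep()].
#' @param xi_star,beta_star the proposal.
#' @param graph a [knn_graph()].
#' @param hyper a [potts_hyperparams()].
#' @return List with `accept` (logical; decided with a seeded uniform) and
#'   `log_r`. A non-finite log ratio rejects with a warning.
#' @export
double_mh_accept <- function(labels, xi, beta, labels_star, xi_star,
                             beta_star, graph, hyper) {
  # instantiate both stick sets far enough to score both label vectors
  Lneed <- max(labels, labels_star)
  xi <- extend_xi_prior(xi, Lneed, hyper$alpha)
  xi_star <- extend_xi_prior(xi_star, Lneed, hyper$alpha)
  pi <- xi_to_pi(xi)
  pi_star <- xi_to_pi(xi_star)
  R0 <- min(hyper$R0, length(xi), length(xi_star))
  i0 <- seq_len(R0)
  s0 <- sqrt(hyper$tau2_0)
  s1 <- sqrt(hyper$tau2_1)
  log_prior <- (hyper$alpha - 1) *
    sum(log1p(-xi_star[i0]) - log1p(-xi[i0])) +
    dtnorm(beta_star, hyper$a_beta, sqrt(hyper$tau2_beta), 0, Inf, log = TRUE) -
    dtnorm(beta, hyper$a_beta, sqrt(hyper$tau2_beta), 0, Inf, log = TRUE)
  log_prop <- sum(dtnorm(xi[i0], xi_star[i0], s0, 0, 1, log = TRUE) -
                  dtnorm(xi_star[i0], xi[i0], s0, 0, 1, log = TRUE)) +
    dtnorm(beta, beta_star, s1, 0, Inf, log = TRUE) -
    dtnorm(beta_star, beta, s1, 0, Inf, log = TRUE)
  S_cur <- directed_agreement(labels, graph)
  S_star <- directed_agreement(labels_star, graph)
  log_exch <- (sum(log(pi_star[labels])) + beta_star * S_cur +
               sum(log(pi[labels_star])) + beta * S_star) -
              (sum(log(pi[labels])) + beta * S_cur +
               sum(log(pi_star[labels_star])) + beta_star * S_star)
  log_r <- log_prior + log_prop + log_exch
  if (!is.finite(log_r)) {
    warning("non-finite exchange log-ratio; proposal rejected")
    return(list(accept = FALSE, log_r = log_r))
  }
  list(accept = log(runif(1)) < log_r, log_r = log_r)
}

extend_xi_prior <- function(xi, L, alpha) {
  if (length(xi) < L) xi <- c(xi, clamp_xi(rbeta(L - length(xi), 1, alpha)))
  xi
}

xi_to_pi <- function(xi) xi * c(1, cumprod(1 - xi)[-length(xi)])

#' Fit the nonparametric spatial Potts cell-typing model
#'
#' Runs the partially collapsed Gibbs sampler: per iteration, (a) a joint
#' exchange (double-MH) update of the interaction strength beta and the
#' stick variables, (b) slice-variable refresh, (c) a sequential
#' slice-restricted label sweep, (d) conjugate update of the emission
#' means, (e) conjugate update of the per-PC variances. Post-burn-in
#' samples are stored (thinned) and summarised into a point clustering via
#' [summarize_labels()]. The run is bit-reproducible given `config$seed`.
#'
#' @param pcs H x n matrix of PC scores from [preprocess_pcs()] (or any
#'   numeric matrix with cells as columns).
#' @param coords cell coordinates (data frame with `x`, `y` or n x 2
#'   matrix); ignored when `graph` is given.
#' @param graph optional prebuilt [knn_graph()].
#' @param k neighbours per cell when building the graph (default 6).
#' @param hyper a [potts_hyperparams()].
#' @param config an [mcmc_config()].
#' @return An object of class `"potts_fit"`: point labels and estimated
#'   cluster count (`point_labels`, `k_hat`), stored draws (`C_samples`,
#'   `beta_samples`, `K_trace`), `accept_rate` of exchange proposals,
#'   invariant diagnostics, and the configuration used. Methods: `print()`,
#'   `tidy()`, `glance()`, `autoplot()`.
#' @export
fit_potts_celltypes <- function(pcs, coords = NULL, graph = NULL, k = 6,
                                hyper = potts_hyperparams(),
                                config = mcmc_config()) {
  Y <- as.matrix(pcs)
  if (is.null(graph)) {
    if (is.null(coords)) stop("supply either coords or a prebuilt graph")
    graph <- knn_graph(coords, k = k)
  }
  if (graph$n != ncol(Y)) {
    stop("graph has ", graph$n, " cells but pcs has ", ncol(Y), " columns")
  }
  set.seed(config$seed)
  state <- initialize_state(Y, graph, hyper, config)
  n <- ncol(Y)
  keep <- seq(config$burn_in + 1, config$n_iter, by = config$thin)
  S <- length(keep)
  C_samples <- if (config$store_labels) matrix(0L, n, S) else NULL
  beta_samples <- numeric(S)
  K_trace <- integer(S)
  n_accept <- 0L
  max_mass_err <- 0
  u_violations <- 0L
  s <- 0L
  t_start <- Sys.time()
  for (it in seq_len(config$n_iter)) {
    # (a) exchange update of (beta, sticks)
    prop <- propose_beta_xi(state$sticks, state$beta, hyper)
    aux <- auxiliary_gibbs_sweep(state$C, prop$xi_star, prop$beta_star,
                                 graph, hyper$alpha)
    state$sticks$xi <- extend_xi_prior(state$sticks$xi,
                                       max(aux$labels_star), hyper$alpha)
    acc <- double_mh_accept(state$C, state$sticks$xi, state$beta,
                            aux$labels_star, aux$xi_star, prop$beta_star,
                            graph, hyper)
    if (acc$accept) {
      state$sticks$xi <- aux$xi_star
      state$beta <- prop$beta_star
      n_accept <- n_accept + 1L
    }
    state$eta <- grow_eta(state$eta, length(state$sticks$xi), hyper)
    # (b) slice variables
    state$u <- sample_u(state$C, state$sticks)
    # (c) labels, with the candidate sets kept finite by stick extension
    state$sticks <- extend_sticks(state$sticks, u_min = min(state$u))
    state$eta <- grow_eta(state$eta, length(state$sticks$xi), hyper)
    state$C <- update_labels(state$C, state$u, Y, graph, state$beta,
                             state$sticks, state$eta, state$sigma2)
    # (d) emission means, (e) variances
    L <- length(state$sticks$xi)
    state$eta <- update_eta(state$C, Y, state$sigma2, L, hyper)
    state$sigma2 <- update_sigma2(state$C, Y, state$eta, hyper)
    if (config$validate) {
      pi <- stick_weights(state$sticks)
      max_mass_err <- max(max_mass_err,
                          abs(sum(pi) + stick_tail_mass(state$sticks) - 1))
      u_violations <- u_violations + sum(state$u > pi[state$C])
    }
    if (it > config$burn_in && (it - config$burn_in - 1) %% config$thin == 0) {
      s <- s + 1L
      if (config$store_labels) C_samples[, s] <- state$C
      beta_samples[s] <- state$beta
      K_trace[s] <- length(unique(state$C))
    }
    if (config$verbose && it %% config$report_every == 0) {
      message(sprintf("iter %d/%d  beta = %.3f  K = %d  accept = %.3f",
                      it, config$n_iter, state$beta,
                      length(unique(state$C)), n_accept / it))
    }
  }
  fit <- structure(
    list(C_samples = C_samples, beta_samples = beta_samples,
         K_trace = K_trace, accept_rate = n_accept / config$n_iter,
         n_accept = n_accept, hyper = hyper, config = config,
         n_cells = n, k = graph$k, cell_ids = colnames(Y),
         final_state = state,
         diagnostics = list(max_mass_err = max_mass_err,
                            u_violations = u_violations),
         runtime_sec = as.numeric(difftime(Sys.time(), t_start,
                                           units = "secs"))),
    class = "potts_fit")
  if (config$store_labels) {
    est <- summarize_labels(fit)
    fit$point_labels <- est$point_labels
    fit$k_hat <- est$k_hat
  }
  fit
}

#' Slice-augmented label-kernel chain at frozen parameters
#'
#' Diagnostic driver iterating only the slice refresh and the sequential
#' label sweep (steps (b) and (c)) at fixed beta, sticks and emission
#' parameters. On enumerable instances its empirical configuration
#' distribution can be compared against [exact_potts_distribution()];
#' flat emissions (equal means, large variance) expose the pure Potts
#' kernel.
#'
#' @inheritParams update_labels
#' @param n_sweeps number of (b)+(c) sweeps to run.
#' @return n x n_sweeps integer matrix: the label vector after every sweep.
#' @export
slice_label_chain <- function(labels, Y, graph, beta, sticks, eta, sigma2,
                              n_sweeps) {
  pi <- stick_weights(sticks)
  out <- label_sweep_cpp(as.integer(labels), as.matrix(Y), eta, sigma2,
                         beta, pi, rep(0.5, length(labels)), graph$nb,
                         graph$in_ptr, graph$in_idx,
                         as.integer(n_sweeps), resample_u = TRUE,
                         store_trace = TRUE)
  out$trace
}

#' Posterior point clustering
#'
#' Aligns every stored label vector to the first stored sample by greedy
#' maximum-overlap label matching (ties resolved toward lower labels,
#' unmatched labels mapped to fresh ones), then takes the per-cell mode of
#' the aligned labels. Deterministic given the chain.
#'
#' @param fit a `"potts_fit"` with stored label samples.
#' @return List with `point_labels` (length-n integer vector) and `k_hat`
#'   (number of distinct labels in the point estimate).
#' @export
summarize_labels <- function(fit) {
  C <- fit$C_samples
  if (is.null(C) || ncol(C) < 1) stop("no stored label samples")
  ref <- C[, 1]
  S <- ncol(C)
  aligned <- matrix(0L, nrow(C), S)
  aligned[, 1] <- ref
  next_label <- max(ref) + 1L
  for (s in seq_len(S)[-1]) {
    aligned[, s] <- align_to_reference(C[, s], ref)
    m <- max(aligned[, s])
    if (m >= next_label) next_label <- m + 1L
  }
  point <- apply(aligned, 1, function(x) {
    tab <- tabulate(x)
    which.max(tab) # ties -> lowest label
  })
  list(point_labels = as.integer(point),
       k_hat = length(unique(point)))
}

# greedy maximum-overlap relabelling of `labels` onto the alphabet of `ref`
align_to_reference <- function(labels, ref) {
  la <- sort(unique(labels))
  lb <- sort(unique(ref))
  tab <- matrix(0L, length(la), length(lb))
  for (i in seq_along(la)) {
    sel <- labels == la[i]
    tab[i, ] <- vapply(lb, function(b) sum(ref[sel] == b), integer(1))
  }
  map <- integer(length(la))
  used_b <- rep(FALSE, length(lb))
  for (step in seq_len(min(length(la), length(lb)))) {
    best <- which(tab == max(tab), arr.ind = TRUE)[1, , drop = TRUE]
    if (tab[best[1], best[2]] <= 0) break
    map[best[1]] <- lb[best[2]]
    used_b[best[2]] <- TRUE
    tab[best[1], ] <- -1L
    tab[, best[2]] <- -1L
  }
  fresh <- max(ref, labels) + 1L
  for (i in seq_along(map)) {
    if (map[i] == 0L) {
      map[i] <- fresh
      fresh <- fresh + 1L
    }
  }
  map[match(labels, la)]
}

#' @export
print.potts_fit <- function(x, ...) {
  cat("Nonparametric spatial Potts cell-typing fit\n")
  cat("  cells:", x$n_cells, "  k =", x$k, "\n")
  cat("  iterations:", x$config$n_iter, "(burn-in", x$config$burn_in,
      ", stored", length(x$beta_samples), ")\n")
  if (!is.null(x$k_hat)) cat("  estimated cell types:", x$k_hat, "\n")
  cat(sprintf("  posterior beta: %.3f (mean)   exchange acceptance: %.3f\n",
              mean(x$beta_samples), x$accept_rate))
  invisible(x)
}
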