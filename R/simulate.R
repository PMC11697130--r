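#' Synthetic spatial-transcriptomics study configuration
#'
#' Parameters of the synthetic-data generator: scattered 2-D cell
#' positions, spatially coherent ground-truth labels drawn from a
#' finite-K Potts model by Gibbs sweeps, and per-cell Gaussian PC-like
#' feature vectors (optionally lifted to overdispersed counts to exercise
#' the preprocessing path). Defaults match the package's reference recovery
#' study: 500 cells, 4 types, interaction strength 1, 5-sigma mean
#' separation, 3 feature dimensions, 6 neighbours.
#'
#' @param n_cells number of cells.
#' @param layout `"uniform"` (i.i.d. uniform on the unit square) or
#'   `"jittered-grid"` (sqrt(n) grid with Gaussian jitter).
#' @param grid_jitter jitter standard deviation in grid-step units for the
#'   jittered-grid layout (default 0.1; 0 gives the exact grid).
#' @param K_true number of generating cell types.
#' @param beta_gen generating Potts interaction strength (>= 0).
#' @param pi_gen length-`K_true` external-field weights (sum to 1).
#' @param k_sim neighbour count of the generating kNN graph.
#' @param H_sim feature dimension.
#' @param mean_separation minimum distance between cluster mean vectors in
#'   units of the emission standard deviation.
#' @param sigma2_gen per-dimension emission variance.
#' @param n_sweeps Gibbs sweeps used to draw the label field.
#' @param emit_counts also emit negative-binomial gene counts over
#'   `5 * H_sim` synthetic genes through a log-linear link.
#' @param nb_dispersion negative-binomial dispersion (`size = 1 /
#'   nb_dispersion`) when emitting counts.
#' @param seed RNG seed used by [simulate_st_data()].
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_cells = 500, layout = c("uniform", "jittered-grid"),
                       K_true = 4, beta_gen = 1,
                       pi_gen = rep(1 / K_true, K_true), k_sim = 6,
                       H_sim = 3, mean_separation = 5, sigma2_gen = 1,
                       n_sweeps = 50, emit_counts = FALSE,
                       nb_dispersion = 0.2, grid_jitter = 0.1, seed = 1) {
  layout <- match.arg(layout)
  stopifnot(n_cells >= 2, K_true >= 1, beta_gen >= 0,
            length(pi_gen) == K_true, abs(sum(pi_gen) - 1) < 1e-8,
            mean_separation >= 0, sigma2_gen > 0, n_sweeps >= 1,
            K_true <= 2^H_sim)
  structure(list(n_cells = as.integer(n_cells), layout = layout,
                 K_true = as.integer(K_true), beta_gen = beta_gen,
                 pi_gen = pi_gen, k_sim = as.integer(k_sim),
                 H_sim = as.integer(H_sim),
                 mean_separation = mean_separation,
                 sigma2_gen = sigma2_gen, n_sweeps = as.integer(n_sweeps),
                 emit_counts = emit_counts, nb_dispersion = nb_dispersion,
                 grid_jitter = grid_jitter, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate cell positions
#'
#' @param cfg a [sim_config()].
#' @return A tibble with `cell_id`, `x`, `y`. Uses the R RNG.
#' @export
simulate_positions <- function(cfg) {
  n <- cfg$n_cells
  if (cfg$layout == "uniform") {
    x <- runif(n)
    y <- runif(n)
  } else {
    side <- ceiling(sqrt(n))
    gx <- (rep(seq_len(side), times = side) - 0.5) / side
    gy <- (rep(seq_len(side), each = side) - 0.5) / side
    x <- gx[seq_len(n)] + rnorm(n, 0, cfg$grid_jitter / side)
    y <- gy[seq_len(n)] + rnorm(n, 0, cfg$grid_jitter / side)
  }
  tibble::tibble(cell_id = paste0("cell", seq_len(n)), x = x, y = y)
}

#' Simulate spatially coherent ground-truth labels
#'
#' Labels are initialised i.i.d. from `pi_gen` and evolved by sequential
#' Gibbs sweeps targeting the finite-K truncated Potts law
#' `P(C_i = l | rest) \propto pi_l exp(beta_gen * a_il)` on the `k_sim`-NN
#' graph, where `a_il` counts matching labels over the interaction
#' neighbourhood (out- and in-edges of the directed kNN relation).
#'
#' @param coords coordinate tibble or matrix.
#' @param cfg a [sim_config()].
#' @param n_sweeps number of sweeps (defaults to `cfg$n_sweeps`).
#' @return Integer label vector in `1..K_true`, with the realised directed
#'   agreement fraction (share of directed neighbour pairs with matching
#'   labels) in attribute `"agreement"`.
#' @export
simulate_potts_labels <- function(coords, cfg, n_sweeps = cfg$n_sweeps) {
  graph <- knn_graph(coords, k = cfg$k_sim)
  n <- graph$n
  C0 <- sample.int(cfg$K_true, n, replace = TRUE, prob = cfg$pi_gen)
  if (cfg$K_true == 1) {
    labels <- rep(1L, n)
  } else if (cfg$beta_gen == 0) {
    labels <- C0
  } else {
    labels <- potts_sim_cpp(C0, graph$nb, graph$in_ptr, graph$in_idx,
                            cfg$beta_gen, cfg$pi_gen,
                            as.integer(n_sweeps), FALSE)$C
  }
  structure(as.integer(labels),
            agreement = directed_agreement(labels, graph) / (n * graph$k))
}

# cluster means on scaled signed binary codes: the first K rows of
# {-1, +1}^H, scaled so the minimum pairwise distance (codes differing in
# one coordinate, i.e. 2 * scale) equals mean_separation * sigma
sim_cluster_means <- function(cfg) {
  codes <- as.matrix(expand.grid(rep(list(c(-1, 1)), cfg$H_sim)))
  codes <- codes[seq_len(cfg$K_true), , drop = FALSE]
  scale <- cfg$mean_separation * sqrt(cfg$sigma2_gen) / 2
  t(codes) * scale # H x K
}

#' Simulate expression features for given labels
#'
#' Gaussian PC-like features `Y_hi ~ N(eta_{h,label(i)}, sigma2_gen)` with
#' cluster means placed on scaled signed binary codes so that the minimum
#' pairwise mean distance is `mean_separation * sqrt(sigma2_gen)`. With
#' `emit_counts = TRUE`, features are additionally mapped through a
#' log-linear link to negative-binomial counts over `5 * H_sim` synthetic
#' genes.
#'
#' @param labels integer labels in `1..K_true`.
#' @param cfg a [sim_config()].
#' @return A list: `pcs` (H x n `"pc_matrix"`-shaped feature matrix),
#'   `means` (H x K generating means), and `counts` (a
#'   `"cell_expression"`, only when `emit_counts`).
#' @export
simulate_expression <- function(labels, cfg) {
  stopifnot(all(labels >= 1), all(labels <= cfg$K_true))
  n <- length(labels)
  eta <- sim_cluster_means(cfg)
  Y <- eta[, labels, drop = FALSE] +
    matrix(rnorm(cfg$H_sim * n, 0, sqrt(cfg$sigma2_gen)), cfg$H_sim, n)
  colnames(Y) <- paste0("cell", seq_len(n))
  rownames(Y) <- paste0("PC", seq_len(cfg$H_sim))
  out <- list(pcs = Y, means = eta)
  if (cfg$emit_counts) {
    # log-linear lift: each synthetic gene loads on a random unit direction
    # of the feature space, around a baseline of ~20 counts
    G <- 5L * cfg$H_sim
    W <- matrix(rnorm(G * cfg$H_sim), G, cfg$H_sim)
    W <- W / sqrt(rowSums(W^2))
    log_mu <- 3 + 0.5 * W %*% (Y / sqrt(cfg$sigma2_gen))
    mu <- exp(pmin(log_mu, 8))
    counts <- matrix(rnbinom2(G * n, mu = as.vector(mu),
                              size = 1 / cfg$nb_dispersion), G, n)
    cm <- t(counts)
    rownames(cm) <- colnames(Y)
    colnames(cm) <- paste0("gene", seq_len(G))
    out$counts <- new_cell_expression(cm, is_count = TRUE)
  }
  out
}

rnbinom2 <- function(n, mu, size) stats::rnbinom(n, mu = mu, size = size)

#' Simulate a complete synthetic dataset
#'
#' Seeds the RNG from `cfg$seed` and chains [simulate_positions()],
#' [simulate_potts_labels()] and [simulate_expression()]. All outputs are
#' reproducible from `(cfg, cfg$seed)`.
#'
#' @param cfg a [sim_config()].
#' @return A list: `coords` (tibble), `labels` (integer vector with
#'   agreement attribute), `pcs` (H x n matrix), `counts` (if requested),
#'   `means`, and the `cfg` used.
#' @export
simulate_st_data <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  coords <- simulate_positions(cfg)
  labels <- simulate_potts_labels(coords, cfg)
  expr <- simulate_expression(labels, cfg)
  list(coords = coords, labels = labels, pcs = expr$pcs,
       counts = expr$counts, means = expr$means, cfg = cfg)
}
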