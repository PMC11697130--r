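test_that("positions respect layout contracts and determinism", {
  cfg <- sim_config(n_cells = 4, layout = "jittered-grid", grid_jitter = 0)
  set.seed(50)
  pos <- simulate_positions(cfg)
  expect_equal(sort(unique(pos$x)), c(0.25, 0.75))
  expect_equal(sort(unique(pos$y)), c(0.25, 0.75))
  cfg2 <- sim_config(n_cells = 200, layout = "uniform")
  set.seed(51)
  p1 <- simulate_positions(cfg2)
  expect_true(all(p1$x >= 0 & p1$x <= 1 & p1$y >= 0 & p1$y <= 1))
  set.seed(51)
  p2 <- simulate_positions(cfg2)
  expect_identical(p1, p2)
})

test_that("labels are i.i.d. from pi_gen when the interaction is off", {
  cfg <- sim_config(n_cells = 1e4, K_true = 3, beta_gen = 0,
                    pi_gen = c(0.5, 0.3, 0.2))
  set.seed(52)
  pos <- simulate_positions(cfg)
  lab <- simulate_potts_labels(pos, cfg)
  freq <- tabulate(lab, 3) / 1e4
  for (l in 1:3) {
    se <- sqrt(cfg$pi_gen[l] * (1 - cfg$pi_gen[l]) / 1e4)
    expect_lt(abs(freq[l] - cfg$pi_gen[l]), 4 * se)
  }
  cfg1 <- sim_config(n_cells = 50, K_true = 1, pi_gen = 1, H_sim = 1)
  set.seed(53)
  lab1 <- simulate_potts_labels(simulate_positions(cfg1), cfg1)
  expect_true(all(lab1 == 1L))
})

test_that("generator label law matches the enumeration oracle on a tiny graph", {
  cfg <- sim_config(n_cells = 5, K_true = 2, beta_gen = 0.8,
                    pi_gen = c(0.6, 0.4), k_sim = 1, H_sim = 1)
  coords <- data.frame(x = 0:4, y = 0)
  g <- line_graph(5)
  ex <- exact_potts_distribution(g, 0.8, cfg$pi_gen)
  set.seed(54)
  # one long chain; simulate_potts_labels wraps the same kernel, so drive
  # the kernel directly to retain the whole trajectory
  out <- spotts:::potts_sim_cpp(rep(1L, 5), g$nb, g$in_ptr, g$in_idx,
                                0.8, cfg$pi_gen, 150000L, TRUE)
  emp <- empirical_config_dist(out$trace, 2L)
  expect_lt(tv_dist(emp, ex$prob), 0.03)
})

test_that("spatial coherence increases with the interaction strength", {
  agree_at_beta <- function(beta, seed) {
    cfg <- sim_config(n_cells = 300, beta_gen = beta, seed = seed)
    set.seed(seed)
    pos <- simulate_positions(cfg)
    attr(simulate_potts_labels(pos, cfg), "agreement")
  }
  betas <- c(0, 0.5, 1, 2)
  mean_agree <- vapply(betas, function(b) {
    mean(vapply(1:10, function(s) agree_at_beta(b, s), numeric(1)))
  }, numeric(1))
  # non-decreasing on average up to the quench plateau of the finite-sweep
  # generator: deep in the ordered phase single-site dynamics freeze into
  # a patchwork whose realised agreement levels off ~0.9 (the dip between
  # beta 1 and 2 measures ~0.01, within the plateau tolerance below)
  expect_true(all(diff(mean_agree) > -0.02))
  expect_gt(mean_agree[4], mean_agree[1] + 0.5)
  expect_gt(mean_agree[2], mean_agree[1] + 0.3)
})

test_that("feature emission honours separation and noise settings", {
  cfg0 <- sim_config(n_cells = 40, K_true = 4, sigma2_gen = 1e-18,
                     mean_separation = 5)
  set.seed(55)
  lab <- sample.int(4, 40, replace = TRUE)
  ex <- simulate_expression(lab, cfg0)
  expect_equal(ex$pcs, ex$means[, lab], tolerance = 1e-6,
               ignore_attr = TRUE)
  # zero separation carries no label signal
  cfg1 <- sim_config(n_cells = 40, K_true = 4, mean_separation = 0)
  ex1 <- simulate_expression(lab, cfg1)
  expect_equal(max(abs(ex1$means)), 0)
  # pairwise mean distances >= separation * sigma
  cfg2 <- sim_config(K_true = 4, H_sim = 3, mean_separation = 5)
  mu <- simulate_expression(c(1L, 2L, 3L, 4L), cfg2)$means
  d <- as.matrix(dist(t(mu)))
  expect_gte(min(d[upper.tri(d)]), 5)
})

test_that("well-separated clusters are recoverable by nearest-mean", {
  cfg <- sim_config(n_cells = 400, K_true = 2, H_sim = 2,
                    mean_separation = 6, beta_gen = 0)
  set.seed(56)
  lab <- sample.int(2, 400, replace = TRUE)
  ex <- simulate_expression(lab, cfg)
  pred <- apply(ex$pcs, 2, function(y) {
    which.min(colSums((ex$means - y)^2))
  })
  expect_lt(mean(pred != lab), 0.01)
})

test_that("count emission round-trips through preprocessing", {
  cfg <- sim_config(n_cells = 300, K_true = 3, H_sim = 3,
                    mean_separation = 5, emit_counts = TRUE, seed = 57)
  sim <- simulate_st_data(cfg)
  expect_true(attr(sim$counts, "is_count"))
  expect_equal(dim(sim$counts), c(300, 15))
  y <- preprocess_pcs(sim$counts, n_pcs = 3)
  set.seed(1)
  km <- kmeans(t(y), centers = 3, nstart = 10)
  expect_gte(adjusted_rand_index(km$cluster, sim$labels), 0.8)
})

test_that("the full simulation is reproducible from its config", {
  cfg <- sim_config(n_cells = 80, seed = 58)
  s1 <- simulate_st_data(cfg)
  s2 <- simulate_st_data(cfg)
  expect_identical(s1$coords, s2$coords)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$pcs, s2$pcs)
})
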