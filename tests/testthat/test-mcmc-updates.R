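test_that("slice variables stay inside their support with uniform moments", {
  s <- binary_sticks(0.5)
  set.seed(30)
  C <- rep(1L, 1e5)
  u <- sample_u(C, s)
  expect_true(all(u > 0 & u < 0.5))
  # mean of Unif(0, 0.5) is 0.25, sd/sqrt(n) gives the Monte Carlo error
  se <- 0.5 / sqrt(12) / sqrt(1e5)
  expect_lt(abs(mean(u) - 0.25), 4 * se)
  # all cells in one cluster share the same upper bound
  expect_true(all(u <= stick_weights(s)[1]))
})

test_that("a singleton candidate set forces the label", {
  g <- line_graph(5)
  s <- binary_sticks(0.6)
  pi <- stick_weights(s)
  Y <- matrix(0, 1, 5)
  eta <- matrix(0, 1, 2)
  set.seed(31)
  # u_i above pi_2 for every cell: only label 1 is admissible
  u <- runif(5, pi[2] + 0.01, pi[1])
  C <- update_labels(rep(2L, 5), u, Y, g, beta = 1, s, eta, sigma2 = 1)
  expect_equal(C, rep(1L, 5))
})

test_that("flat instances split evenly between symmetric candidates", {
  g <- line_graph(5)
  s <- binary_sticks(0.5)
  Y <- matrix(0, 1, 5)
  eta <- matrix(0, 1, 2) # equal emissions
  set.seed(32)
  picks <- replicate(2000, {
    u <- sample_u(rep(1L, 5), s)
    update_labels(rep(1L, 5), u, Y, g, beta = 0, s, eta, sigma2 = 1)[3]
  })
  p_hat <- mean(picks == 1)
  expect_lt(abs(p_hat - 0.5), 4 * sqrt(0.25 / 2000))
})

test_that("spatial coupling dominates as printed in the full conditional", {
  # focal cell far from a tight 7-cell cluster: it has 6 out-neighbours,
  # no in-neighbours, so its conditional is exp(beta * 6) vs 1 at equal
  # emissions -> P(label 1) = e^12 / (e^12 + 1) at beta = 2
  set.seed(33)
  xy <- rbind(cbind(rnorm(7, 0, 0.01), rnorm(7, 0, 0.01)), c(10, 10))
  g <- knn_graph(xy, k = 6)
  expect_equal(g$in_ptr[9] - g$in_ptr[8], 0L) # no in-edges to cell 8
  s <- binary_sticks(0.5)
  Y <- matrix(0, 1, 8)
  eta <- matrix(0, 1, 2)
  labs <- replicate(300, {
    u <- rep(1e-6, 8) # both labels always candidates
    update_labels(c(rep(1L, 7), 2L), u, Y, g, beta = 2, s, eta, 1)[8]
  })
  # P(all 300 draws = 1) = (e^12/(e^12+1))^300 > 0.998
  expect_true(all(labs == 1L))
})

test_that("emission mean updates reproduce the conjugate posterior", {
  hyper <- potts_hyperparams(a_eta = 0, b2_eta = 1)
  # m = 0: prior recovery (forced by the formula)
  set.seed(34)
  draws0 <- replicate(2e4, update_eta(labels = c(1L, 1L),
                                      Y = matrix(c(2, 2), 1, 2),
                                      sigma2 = 1, L = 2, hyper)[1, 2])
  expect_lt(abs(mean(draws0) - 0), 4 / sqrt(2e4))
  expect_lt(abs(var(draws0) - 1), 4 * sqrt(2 / 2e4))
  # m = 1, Y = 2, sigma2 = 1: posterior N(1, 1/2)
  draws1 <- replicate(2e4, update_eta(labels = 1L, Y = matrix(2, 1, 1),
                                      sigma2 = 1, L = 1, hyper)[1, 1])
  expect_lt(abs(mean(draws1) - 1), 4 * sqrt(0.5) / sqrt(2e4))
  expect_lt(abs(var(draws1) - 0.5), 4 * 0.5 * sqrt(2 / 2e4))
  # general plug-in check of the posterior parameters at H = 2, L = 3
  Y <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  lab <- c(1L, 2L, 2L)
  s2 <- c(2, 0.5)
  hy <- potts_hyperparams(a_eta = 1, b2_eta = 4)
  set.seed(35)
  d <- replicate(2e4, update_eta(lab, Y, s2, 3, hy)[1, 2])
  prec <- 2 / s2[1] + 1 / 4
  mu <- ((3 + 5) / s2[1] + 1 / 4) / prec
  expect_lt(abs(mean(d) - mu), 4 / sqrt(prec) / sqrt(2e4))
  expect_lt(abs(var(d) - 1 / prec), 4 * (1 / prec) * sqrt(2 / 2e4))
})

test_that("variance updates draw from the printed inverse gamma", {
  # residuals all zero, kappa = 2, tau = 1, n = 4 -> inv-Gamma(4, 1)
  hyper <- potts_hyperparams(kappa = 2, tau = 1)
  Y <- matrix(1, 1, 4)
  eta <- matrix(1, 1, 1)
  set.seed(36)
  d <- replicate(5e4, update_sigma2(rep(1L, 4), Y, eta, hyper))
  m_true <- 1 / 3                      # scale / (shape - 1)
  v_true <- 1 / (9 * 2)                # scale^2 / ((a-1)^2 (a-2))
  expect_lt(abs(mean(d) - m_true), 4 * sqrt(v_true / 5e4))
  # kappa = 3, tau = 2, rss = 6, n = 2 -> inv-Gamma(4, 5)
  hy2 <- potts_hyperparams(kappa = 3, tau = 2)
  Y2 <- matrix(c(1, -1), 1, 2)         # eta 0 -> rss = 2... use scaled Y
  Y2 <- matrix(c(sqrt(3), -sqrt(3)), 1, 2) # rss = 6
  set.seed(37)
  d2 <- replicate(1e5, update_sigma2(rep(1L, 2), Y2, matrix(0, 1, 1), hy2))
  expect_lt(abs(mean(d2) - 5 / 3), 4 * sqrt((25 / 18) / 1e5))
})

test_that("initialisation is deterministic and recovers separated clouds", {
  set.seed(38)
  n <- 60
  lab_true <- rep(1:2, each = n / 2)
  Y <- matrix(rnorm(2 * n, sd = 0.3), 2, n) + rbind(c(rep(0, 30), rep(6, 30)),
                                                    0)
  g <- knn_graph(matrix(runif(2 * n), ncol = 2), k = 3)
  hyper <- potts_hyperparams()
  set.seed(99)
  st <- initialize_state(Y, g, hyper, mcmc_config(init_k = 2))
  expect_equal(adjusted_rand_index(st$C, lab_true), 1)
  expect_true(all(st$u <= stick_weights(st$sticks)[st$C]))
  expect_gte(length(st$sticks$xi), hyper$R0)
  expect_equal(ncol(st$eta), length(st$sticks$xi))
  set.seed(99)
  st2 <- initialize_state(Y, g, hyper, mcmc_config(init_k = 2))
  expect_identical(st, st2)
  # degenerate single-cluster init
  set.seed(99)
  st1 <- initialize_state(Y, g, hyper, mcmc_config(init_k = 1))
  expect_true(all(st1$C == 1L))
  expect_equal(st1$eta[, 1], rowMeans(Y))
  expect_error(initialize_state(Y, g, hyper, mcmc_config(init_k = 61)),
               "exceeds")
})
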