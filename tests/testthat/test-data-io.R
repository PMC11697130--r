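test_that("dense expression files round-trip exactly", {
  m <- matrix(c(0L, 3L, 1L, 7L, 2L, 5L), nrow = 3,
              dimnames = list(paste0("c", 1:3), paste0("g", 1:2)))
  expr <- new_cell_expression(m)
  expect_true(attr(expr, "is_count"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_expression(expr, path)
  back <- read_expression(path)
  expect_equal(unclass(back)[, ], unclass(expr)[, ])
  expect_equal(dim(back), c(3, 2))
})

test_that("genes-in-rows orientation is transposed on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,c1,c2,c3", "g1,1,2,3", "g2,4,5,6"), path)
  e <- read_expression(path, orientation = "genes-rows")
  expect_equal(dim(e), c(3, 2))
  expect_equal(unname(unclass(e)["c2", "g2"]), 5)
})

test_that("matrix-market input handles empty matrices and sidecars", {
  path <- withr::local_tempfile(fileext = ".mtx")
  gf <- withr::local_tempfile()
  cf <- withr::local_tempfile()
  m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(4, 3)) # genes x cells, 0 stored entries
  Matrix::writeMM(m, path)
  writeLines(paste0("g", 1:4), gf)
  writeLines(paste0("c", 1:3), cf)
  e <- read_expression(path, genes_file = gf, cells_file = cf)
  expect_equal(dim(e), c(3, 4))
  expect_true(all(e == 0))
  writeLines(paste0("g", 1:5), gf)
  expect_error(read_expression(path, genes_file = gf, cells_file = cf),
               "gene id")
})

test_that("sparse write/read round-trips integer counts bitwise", {
  set.seed(10)
  m <- matrix(rpois(40, 2), nrow = 5,
              dimnames = list(paste0("c", 1:5), paste0("g", 1:8)))
  expr <- new_cell_expression(m)
  path <- withr::local_tempfile(fileext = ".mtx")
  gf <- withr::local_tempfile()
  cf <- withr::local_tempfile()
  write_expression(expr, path, genes_file = gf, cells_file = cf)
  back <- read_expression(path, genes_file = gf, cells_file = cf)
  expect_identical(unclass(back)[, ], unclass(expr)[, ] + 0)
})

test_that("expression validation catches malformed input", {
  expect_error(new_cell_expression(matrix(c(1, NA), 1)), "missing")
  m <- matrix(1:4, 2, dimnames = list(c("a", "a"), c("g1", "g2")))
  expect_error(new_cell_expression(m), "duplicated cell ids")
  expect_error(new_cell_expression(matrix(c(1.5, -2, 0, 1), 2),
                                   is_count = TRUE), "nonnegative integers")
})

test_that("coordinates parse, reject NaN, and realign to cell ids", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,x,y", "a,0,0", "b,1,0.5", "c,2,1"), path)
  co <- read_coordinates(path)
  expect_equal(co$x, c(0, 1, 2))
  co2 <- read_coordinates(path, cell_ids = c("c", "a", "b"))
  expect_equal(co2$cell_id, c("c", "a", "b"))
  expect_equal(co2$x, c(2, 0, 1))
  expect_error(read_coordinates(path, cell_ids = c("a", "zz")), "missing")
  writeLines(c("id,x,y", "a,0,NaN"), path)
  expect_error(read_coordinates(path), "finite")
  writeLines(c("id,x,y", "a,0,oops"), path)
  expect_error(read_coordinates(path), "non-numeric")
})

test_that("labels round-trip with id alignment", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_labels(c(2, 1, 1), c("a", "b", "c"), path)
  lab <- read_labels(path, cell_ids = c("b", "c", "a"))
  expect_equal(lab$label, c(1L, 1L, 2L))
})

test_that("exact low-rank data is recovered by the PC projection", {
  set.seed(11)
  n <- 30
  plane <- cbind(rnorm(n), rnorm(n))            # true 2-D scores
  basis <- qr.Q(qr(matrix(rnorm(8 * 2), 8)))    # orthonormal lift to 8 dims
  m <- plane %*% t(basis)
  expr <- new_cell_expression(m, is_count = FALSE)
  y <- preprocess_pcs(expr, n_pcs = 3, normalize = FALSE,
                      log_transform = FALSE)
  ve <- attr(y, "var_explained")
  expect_lt(ve[3], 1e-10)                        # nothing beyond the plane
  # distances between cells are preserved by the top-2 projection
  d0 <- dist(scale(plane, scale = FALSE))
  d1 <- dist(t(y[1:2, ]))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-8)
})

test_that("library-size normalisation collapses proportional cells", {
  m <- matrix(c(1, 2, 4, 8,
                2, 4, 8, 16,
                3, 6, 12, 24) * 2, nrow = 3, byrow = TRUE)
  m <- cbind(m, m[, 1]) # 5 genes
  expr <- new_cell_expression(m)
  y <- preprocess_pcs(expr, n_pcs = 2, normalize = TRUE,
                      log_transform = TRUE)
  expect_lt(max(abs(y)), 1e-10)
})

test_that("PC scores match an independent eigendecomposition", {
  set.seed(12)
  m <- matrix(rpois(200, 5), nrow = 20)
  expr <- new_cell_expression(m)
  y <- preprocess_pcs(expr, n_pcs = 4)
  # oracle: normalise/log by hand, eigendecompose the covariance directly
  x <- unclass(m) + 0
  x <- log1p(x / rowSums(x) * median(rowSums(x)))
  xc <- scale(x, scale = FALSE)
  eg <- eigen(crossprod(xc) / (nrow(x) - 1), symmetric = TRUE)
  for (h in 1:4) {
    v <- eg$vectors[, h]
    v <- v * sign(v[which.max(abs(v))])
    expect_equal(unname(y[h, ]), unname(as.vector(xc %*% v)),
                 tolerance = 1e-8)
  }
  # per-PC centring and ordered explained variance
  expect_lt(max(abs(rowMeans(y))), 1e-8)
  expect_true(all(diff(attr(y, "var_explained")) <= 1e-12))
})

test_that("preprocessing commutes with cell permutation", {
  set.seed(13)
  m <- matrix(rpois(150, 4), nrow = 15,
              dimnames = list(paste0("c", 1:15), paste0("g", 1:10)))
  y0 <- preprocess_pcs(new_cell_expression(m), n_pcs = 3)
  p <- sample(15)
  y1 <- preprocess_pcs(new_cell_expression(m[p, ]), n_pcs = 3)
  expect_equal(unname(y1[, ]), unname(y0[, p]), tolerance = 1e-10)
})

test_that("preprocessing rejects impossible requests", {
  m <- matrix(rpois(20, 3) + 1, nrow = 4)
  expect_error(preprocess_pcs(new_cell_expression(m), n_pcs = 4),
               "achievable maximum 3")
  m[2, ] <- 0
  expect_error(preprocess_pcs(new_cell_expression(m), n_pcs = 2),
               "zero total count")
  mm <- matrix(runif(20) + 0.5, nrow = 4)
  expect_warning(preprocess_pcs(new_cell_expression(mm), n_pcs = 2),
                 "non-count")
})
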