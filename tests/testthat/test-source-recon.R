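test_that("regularization follows lambda2 = 1/SNR with the alternative convention available", {
  cfg <- inverse_config()
  expect_equal(cfg$snr, 3)
  expect_equal(cfg$lambda2, 1 / 3)
  expect_equal(inverse_config(snr = 3, lambda_convention = "inverse_snr2")$lambda2, 1 / 9)
  expect_error(inverse_config(snr = 3, lambda2 = 0.5), "conflicts")
  expect_silent(inverse_config(snr = 3, lambda2 = 1 / 3))
})

test_that("minimum-norm operator approaches the identity / true inverse as lambda2 -> 0", {
  cfg <- inverse_config(snr = 1e12, depth_exponent = 0)
  W <- compute_inverse_operator(diag(4), diag(4), cfg)
  expect_lt(max(abs(W - diag(4))), 1e-4)

  set.seed(4)
  G <- matrix(rnorm(25), 5, 5)
  W2 <- compute_inverse_operator(G, diag(5), inverse_config(snr = 1e10, depth_exponent = 0))
  expect_lt(max(abs(W2 - solve(G))), 1e-4)
})

test_that("toy-system inversion localizes a single active source", {
  G <- matrix(c(1.0, 0.2,
                0.3, 1.1,
                0.5, 0.6), 3, 2, byrow = TRUE)
  cfg <- inverse_config(depth_exponent = 0)
  W <- compute_inverse_operator(G, diag(3), cfg)
  for (s in 1:2) {
    x <- G[, s]           # noiseless data from source s
    est <- W %*% x
    expect_equal(which.max(abs(est)), s)
    # matches the Tikhonov least-squares oracle min ||Gz - x||^2 + l2 ||z||^2
    oracle <- solve(crossprod(G) + cfg$lambda2 * diag(2), crossprod(G, x))
    expect_equal(as.vector(est), as.vector(oracle), tolerance = 1e-10)
  }
})

test_that("increasing lambda2 monotonically shrinks the inverse solution", {
  set.seed(5)
  G <- matrix(rnorm(12), 4, 3)
  x <- rnorm(4)
  norms <- vapply(c(0.01, 0.33, 10), function(l2) {
    W <- compute_inverse_operator(G, diag(4),
                                  inverse_config(snr = 1 / l2, depth_exponent = 0))
    sqrt(sum((W %*% x)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("depth weighting normalizes source weights and covariance is regularized", {
  G <- cbind(c(10, 0, 0), c(0, 1, 0), c(0, 0, 0.1))
  cfg <- inverse_config(depth_exponent = 0.5)
  # deep (weak-gain) source gets relative weight 1 after normalization:
  # check via the operator's row responses to its own forward field
  W <- compute_inverse_operator(G, diag(3), cfg)
  expect_equal(dim(W), c(3, 3))

  C_singular <- matrix(1, 3, 3)   # rank 1
  expect_message(compute_inverse_operator(G, C_singular, cfg), "diagonal loading")
  expect_error(compute_inverse_operator(matrix(0, 2, 2), diag(2), cfg), "all-zero")
  expect_error(compute_inverse_operator(G, diag(4), cfg))
})

test_that("inverse application is linear and validates dimensions", {
  set.seed(6)
  G <- matrix(rnorm(12), 4, 3)
  W <- compute_inverse_operator(G, diag(4), inverse_config())
  expect_equal(apply_inverse(matrix(0, 4, 10), W, fs = 100)$data,
               matrix(0, 3, 10), ignore_attr = TRUE)
  x <- matrix(rnorm(40), 4, 10); y <- matrix(rnorm(40), 4, 10)
  lhs <- apply_inverse(2 * x + 3 * y, W, fs = 100)$data
  rhs <- 2 * apply_inverse(x, W, fs = 100)$data + 3 * apply_inverse(y, W, fs = 100)$data
  expect_lt(max(abs(lhs - rhs)), 1e-10)
  expect_error(apply_inverse(matrix(0, 5, 10), W, fs = 100), "sensors")
})

test_that("ROI averaging is the arithmetic mean of member sources", {
  src <- roi_ts(rbind(a = 1:10, b = 1:10, c = -(1:10), d = 21:30), 100)
  parc <- list(one = 4L, same = c(1L, 2L), cancel = c(1L, 3L))
  out <- roi_average(src, parc)
  expect_equal(out$data["one", ], 21:30, ignore_attr = TRUE)
  expect_equal(out$data["same", ], 1:10, ignore_attr = TRUE)
  # opposite-orientation members cancel under plain averaging (documented)
  expect_equal(out$data["cancel", ], rep(0, 10), ignore_attr = TRUE)
  expect_error(roi_average(src, list(empty = integer(0))), "empty")
  expect_error(roi_average(src, list(bad = 99L)), "invalid")
  expect_length(dmn_roi_names(), 12)
})
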