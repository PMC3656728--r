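test_that("activity deltas solve the 2x2 main-effect system", {
  expect_equal(activity_deltas(diag(2), c(0, 0))$delta, c(0, 0))
  expect_equal(activity_deltas(diag(2), c(0.3, 0.1))$delta, c(0.3, 0.1))

  # forward-multiply oracle: beta_int := M delta* recovers delta*
  set.seed(17)
  for (i in 1:50) {
    M <- matrix(rnorm(4, sd = 1), 2, 2) + 2 * diag(2)
    dstar <- rnorm(2)
    out <- activity_deltas(M, M %*% dstar)
    expect_identical(out$status, "estimable")
    expect_lt(max(abs(out$delta - dstar)), 1e-12)
  }

  # collinear main-effect signatures are singular, not inverted
  sing <- activity_deltas(matrix(c(1, 2, 2, 4), 2, 2), c(0.1, 0.2))
  expect_identical(sing$status, "singular")
  expect_true(all(is.na(sing$delta)))
  near <- activity_deltas(cbind(c(1, 1), c(1, 1 + 1e-12)), c(0.1, 0.2))
  expect_identical(near$status, "singular")
})

test_that("influence coefficients evaluate the directed map with pole guard", {
  expect_equal(influence_coefficients(c(0, 0))$m, c(0, 0))
  expect_equal(influence_coefficients(c(0.5, 0))$m, c(0.5, 0))
  expect_equal(influence_coefficients(c(0.2, 0.3))$m, c(0.2 / 1.3, 0.3 / 1.2))
  pole <- influence_coefficients(c(0.5, -1 + 1e-12))
  expect_identical(pole$status, "pole")
  expect_true(all(is.na(pole$m)))
  # a non-estimable upstream status propagates
  passed <- influence_coefficients(list(delta = NULL, status = "singular"))
  expect_identical(passed$status, "singular")
})

test_that("the reparametrization round-trips exactly", {
  set.seed(23)
  worst <- 0
  for (i in 1:1000) {
    M <- matrix(runif(4, -1.5, 1.5), 2, 2)
    if (abs(det(M)) < 0.3) M <- M + 2 * diag(2)
    gamma <- runif(2, -1, 1)
    ad <- activity_deltas(M, gamma)
    ic <- influence_coefficients(ad$delta)
    # m -> delta -> beta_int reproduces the interaction coefficients
    m <- ic$m
    denom <- 1 - m[1] * m[2]
    d_back <- c(m[1] * (1 + m[2]), m[2] * (1 + m[1])) / denom
    worst <- max(worst, max(abs(M %*% d_back - gamma)))
  }
  expect_lt(worst, 1e-10)
})

test_that("label swap and common rescaling act as expected on influences", {
  set.seed(29)
  for (i in 1:25) {
    M <- matrix(runif(4, -1, 1), 2, 2) + 2 * diag(2)
    gamma <- runif(2, -0.5, 0.5)
    m <- influence_coefficients(activity_deltas(M, gamma)$delta)$m
    # swapping the two knockdowns swaps the directed influences
    m_sw <- influence_coefficients(activity_deltas(M[, 2:1], gamma)$delta)$m
    expect_equal(m_sw, rev(m))
    # a common rescaling of all coefficients cancels
    s <- runif(1, 0.2, 5)
    m_sc <- influence_coefficients(activity_deltas(s * M, s * gamma)$delta)$m
    expect_lt(max(abs(m_sc - m)), 1e-12)
  }
})

test_that("analytic influence gradients match central finite differences", {
  set.seed(31)
  for (i in 1:20) {
    theta <- c(runif(4, -1, 1) + 2 * c(1, 0, 0, 1), runif(2, -0.5, 0.5))
    J <- influscreen:::.influence_gradient(theta)$J
    f <- function(th) {
      d <- solve(matrix(th[1:4], 2, 2), th[5:6])
      c(d[1] / (1 + d[2]), d[2] / (1 + d[1]))
    }
    h <- 1e-6
    J_fd <- vapply(1:6, function(k) {
      e <- replace(numeric(6), k, h)
      (f(theta + e) - f(theta - e)) / (2 * h)
    }, numeric(2))
    expect_lt(max(abs(J - J_fd) / pmax(abs(J_fd), 1)), 1e-6)
  }
})

test_that("propagated variance matches a Monte-Carlo oracle at small perturbations", {
  set.seed(37)
  theta0 <- c(1.1, 0.25, -0.2, 0.95, 0.3, -0.15)
  A <- matrix(rnorm(36), 6, 6)
  Sigma <- crossprod(A) * (1e-3)^2 / 6
  pm <- list(theta = theta0, Sigma = Sigma)
  v <- influence_variance(pm)

  n_draw <- 1e5
  draws <- matrix(rnorm(n_draw * 6), n_draw, 6) %*% chol(Sigma)
  ms <- vapply(seq_len(n_draw), function(i) {
    th <- theta0 + draws[i, ]
    d <- solve(matrix(th[1:4], 2, 2), th[5:6])
    c(d[1] / (1 + d[2]), d[2] / (1 + d[1]))
  }, numeric(2))
  emp <- c(var(ms[1, ]), var(ms[2, ]))
  expect_lt(max(abs(emp - v$var_m) / v$var_m), 0.10)
})

test_that("influence_variance validates its covariance input", {
  pm <- list(theta = c(1, 0, 0, 1, 0.2, 0.1), Sigma = matrix(0, 6, 6))
  expect_equal(influence_variance(pm)$var_m, c(0, 0))
  bad <- diag(6)
  bad[1, 1] <- -1
  expect_error(
    influence_variance(list(theta = c(1, 0, 0, 1, 0.2, 0.1), Sigma = bad)),
    class = "influscreen_validation_error"
  )
})

test_that("pair_influence assembles a consistent one-row summary", {
  scr <- prepared_screen(G = 8, n_strong = 4, n_edges = 1, seed = 71)
  pm <- pair_scan(scr$dataset, scr$decomp, NULL, "g01", "g04")
  out <- pair_influence(pm)
  expect_identical(out$status, "estimable")
  # internal consistency of the reported triple
  expect_lt(abs(out$stat_ab - out$m_ab / out$se_ab), 1e-10)
  # the deltas reproduce the fitted interaction coefficients
  M <- rbind(pm$theta[c(1, 3)], pm$theta[c(2, 4)])
  expect_lt(max(abs(M %*% c(out$delta_1, out$delta_2) - pm$theta[5:6])), 1e-10)
})
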