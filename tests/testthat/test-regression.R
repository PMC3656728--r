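test_that("single-locus scan matches an independent least-squares fit", {
  scr <- prepared_screen(G = 8, n_strong = 3, seed = 21)
  scan <- single_locus_scan(scr$dataset, scr$decomp)
  x <- scr$dataset$genotype
  for (j in 1:2) {
    for (g in c(1, 4, 8)) {
      fit <- summary(lm(scr$decomp$U[, j] ~ x[, g]))
      row <- scan[scan$gene == colnames(x)[g] & scan$eigentrait == j, ]
      expect_lt(abs(row$beta - fit$coefficients[2, 1]), 1e-10)
      expect_lt(abs(row$se - fit$coefficients[2, 2]), 1e-10)
      expect_lt(abs(row$stat - fit$coefficients[2, 3]), 1e-8)
    }
  }
})

test_that("an exact linear eigentrait response is recovered without error", {
  G <- 6
  design <- generate_all_pairs_design(G)
  x <- as.matrix(design[, -1])
  ds <- kd_dataset(design,
    tibble::tibble(line_id = design$line_id, p1 = 1, p2 = 1),
    normalized = TRUE
  )
  dec <- fake_decomp(
    U = cbind(0.5 * x[, 2] + 0.1, 0.2 * x[, 5] - 0.3),
    d = c(1, 1), V = diag(2), k = 2
  )
  scan <- single_locus_scan(ds, dec)
  expect_lt(abs(scan$beta[scan$gene == "g02" & scan$eigentrait == 1] - 0.5), 1e-10)
  expect_lt(abs(scan$beta[scan$gene == "g05" & scan$eigentrait == 2] - 0.2), 1e-10)
})

test_that("null genotype columns give sub-threshold scan statistics", {
  set.seed(14)
  n <- 500
  x <- matrix(rbinom(n * 40, 1, 0.2), n, 40, dimnames = list(NULL, sprintf("g%02d", 1:40)))
  ds <- kd_dataset(
    tibble::tibble(line_id = as.character(1:n), tibble::as_tibble(x)),
    tibble::tibble(line_id = as.character(1:n), p1 = 1, p2 = 1),
    normalized = TRUE
  )
  dec <- fake_decomp(U = matrix(rnorm(2 * n), n, 2), d = c(1, 1), V = diag(2), k = 2)
  scan <- single_locus_scan(ds, dec)
  expect_gte(mean(abs(scan$stat) < 4), 0.98)
})

test_that("strong-effect covariate selection recovers planted strong genes", {
  scr <- prepared_screen(G = 20, n_strong = 5, seed = 3)
  scan <- single_locus_scan(scr$dataset, scr$decomp)
  set.seed(8)
  null <- single_scan_null(scr$dataset, scr$decomp, n_perm = 150)
  cv <- select_covariates(scan, null, alpha = 0.001)
  truth <- scr$sim$truth_main
  # each strong gene's major-axis component must be picked on that eigentrait
  major_et1 <- truth$gene[abs(truth$et1) > abs(truth$et2) & truth$et1 != 0]
  major_et2 <- truth$gene[abs(truth$et2) > abs(truth$et1)]
  expect_setequal(cv$gene_names[cv$sets[[1]]], major_et1)
  expect_setequal(cv$gene_names[cv$sets[[2]]], major_et2)
  expect_error(select_covariates(scan, null, alpha = 2), class = "influscreen_domain_error")

  # nothing selected when the threshold is unreachable
  null_hi <- null
  null_hi$evd_params["location"] <- 1e6
  cv0 <- select_covariates(scan, null_hi, alpha = 0.001)
  expect_identical(lengths(cv0$sets), c(eigentrait_1 = 0L, eigentrait_2 = 0L))
})

test_that("pair scan matches the normal-equations oracle including covariances", {
  scr <- prepared_screen(G = 9, n_strong = 4, n_edges = 2, seed = 31)
  scan <- single_locus_scan(scr$dataset, scr$decomp)
  set.seed(4)
  null <- single_scan_null(scr$dataset, scr$decomp, n_perm = 120)
  cv <- select_covariates(scan, null, alpha = 0.01)
  pm <- pair_scan(scr$dataset, scr$decomp, cv, "g02", "g07")
  expect_identical(pm$status, "estimable")

  x <- scr$dataset$genotype
  for (j in 1:2) {
    covs <- setdiff(cv$sets[[j]], c(2, 7))
    X <- cbind(1, x[, covs, drop = FALSE], x[, 2], x[, 7], x[, 2] * x[, 7])
    y <- scr$decomp$U[, j]
    XtXinv <- solve(crossprod(X))
    beta <- XtXinv %*% crossprod(X, y)
    p <- ncol(X)
    resid <- y - X %*% beta
    s2 <- sum(resid^2) / (nrow(X) - p)
    idx <- c(p - 2, p - 1, p) # xa, xb, xab
    theta_j <- pm$theta[c(j, j + 2, j + 4)]
    expect_lt(max(abs(theta_j - beta[idx])), 1e-8)
    Sj <- pm$Sigma[c(j, j + 2, j + 4), c(j, j + 2, j + 4)]
    expect_lt(max(abs(Sj - s2 * XtXinv[idx, idx])), 1e-8)
  }
  # covariance is symmetric PSD
  expect_lt(max(abs(pm$Sigma - t(pm$Sigma))), 1e-12)
  expect_gte(min(eigen(pm$Sigma, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("noiseless additive data yield exactly zero interaction coefficients", {
  scr <- prepared_screen(G = 8, n_strong = 4, n_edges = 0, seed = 41, noise_sd = 0)
  pm <- pair_scan(scr$dataset, scr$decomp, NULL, "g01", "g02")
  expect_lt(max(abs(pm$theta[c("gamma_1", "gamma_2")])), 1e-10)
})

test_that("a covariate orthogonal to the pair and response leaves the interaction unchanged", {
  set.seed(51)
  G <- 8
  design <- generate_all_pairs_design(G)
  x <- as.matrix(design[, -1])
  n <- nrow(x)
  U <- matrix(rnorm(2 * n), n, 2)
  # build a column orthogonal to xa, xb, xab, intercept and both responses
  basis <- cbind(1, x[, 1], x[, 2], x[, 1] * x[, 2], U)
  z <- residuals(lm(rnorm(n) ~ basis))
  x2 <- cbind(x[, 1:2], ortho = z - min(z))
  x2 <- x2 / max(x2)
  ds <- kd_dataset(
    tibble::tibble(line_id = design$line_id, tibble::as_tibble(x2)),
    tibble::tibble(line_id = design$line_id, p1 = 1, p2 = 1),
    normalized = TRUE
  )
  dec <- fake_decomp(U = U, d = c(1, 1), V = diag(2), k = 2)
  bare <- pair_scan(ds, dec, NULL, 1, 2)
  cv <- structure(
    list(
      sets = list(eigentrait_1 = 3L, eigentrait_2 = 3L),
      threshold = 0, alpha = 1e-3, gene_names = colnames(x2)
    ),
    class = "kd_covariates"
  )
  with_cov <- pair_scan(ds, dec, cv, 1, 2)
  expect_identical(with_cov$status, "estimable")
  # the added column spans only the orthogonal direction (plus the
  # intercept already present), so the interaction estimate is unmoved
  expect_lt(
    max(abs(bare$theta[c("gamma_1", "gamma_2")] - with_cov$theta[c("gamma_1", "gamma_2")])),
    1e-10
  )
})

test_that("pairs that never co-occur are flagged non-estimable", {
  g <- tibble::tibble(
    line_id = c("a", "b", "c", "d", "e"),
    g1 = c(1, 1, 0, 0, 0),
    g2 = c(0, 0, 1, 1, 0),
    g3 = c(1, 0, 1, 0, 1)
  )
  p <- tibble::tibble(line_id = g$line_id, p1 = 1, p2 = 1)
  ds <- kd_dataset(g, p, normalized = TRUE)
  dec <- fake_decomp(U = matrix(rnorm(10), 5, 2), d = c(1, 1), V = diag(2), k = 2)
  pm <- pair_scan(ds, dec, NULL, "g1", "g2")
  expect_identical(pm$status, "non_estimable")
  expect_equal(nrow(tidy(pm)), 0L)
})

test_that("bulk engine agrees with the per-pair reference path", {
  scr <- prepared_screen(G = 8, n_strong = 4, n_edges = 2, seed = 61)
  scan <- single_locus_scan(scr$dataset, scr$decomp)
  set.seed(5)
  null <- single_scan_null(scr$dataset, scr$decomp, n_perm = 120)
  cv <- select_covariates(scan, null, alpha = 0.01)
  pr <- scan_all_pairs(scr$dataset, scr$decomp, cv, n_perm = 0)
  for (i in sample.int(nrow(pr$influences), 8)) {
    row <- pr$influences[i, ]
    ref <- pair_influence(pair_scan(scr$dataset, scr$decomp, cv, row$gene_a, row$gene_b))
    expect_identical(row$status, ref$status)
    if (row$status == "estimable") {
      expect_lt(abs(row$m_ab - ref$m_ab), 1e-8)
      expect_lt(abs(row$m_ba - ref$m_ba), 1e-8)
      expect_lt(abs(row$se_ab - ref$se_ab), 1e-8)
      expect_lt(abs(row$stat_ba - ref$stat_ba), 1e-6)
    }
  }
})
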