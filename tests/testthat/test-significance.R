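test_that("empirical p-values use the add-one permutation rule", {
  nulls <- seq_len(700) / 100 # |stats| 0.01 .. 7
  expect_equal(empirical_pvalue(10, nulls), 1 / 701)
  expect_equal(empirical_pvalue(0.001, nulls), 1)
  # exactly 350 nulls at or above the observed value
  expect_equal(empirical_pvalue(3.51, nulls), (350 + 1) / 701)
  expect_error(empirical_pvalue(1, numeric(0)), class = "influscreen_validation_error")
  # sign is ignored
  expect_equal(empirical_pvalue(-10, nulls), 1 / 701)
})

test_that("Gumbel maximum-likelihood fit recovers known parameters", {
  set.seed(43)
  u <- runif(2000)
  x <- 3 - 0.5 * log(-log(u)) # Gumbel(location 3, scale 0.5) by inversion
  fit <- fit_gumbel(x)
  expect_lt(abs(fit["location"] - 3), 0.05)
  expect_lt(abs(fit["scale"] - 0.5), 0.04)
})

test_that("EVD thresholds are upper quantiles, monotone in alpha", {
  null <- structure(
    list(
      n_perm = 500, max_stats = NULL,
      evd_params = c(location = 3, scale = 0.5), seed = 1
    ),
    class = "kd_scan_null"
  )
  # closed-form Gumbel quantile
  expect_equal(evd_threshold(null, 0.001), 3 - 0.5 * log(-log(0.999)))
  alphas <- c(0.2, 0.05, 0.01, 0.001)
  expect_true(all(diff(vapply(alphas, evd_threshold, numeric(1), null = null)) > 0))
  expect_error(evd_threshold(null, 0), class = "influscreen_domain_error")
})

test_that("the permutation null refuses unstable sizes and is reproducible", {
  scr <- prepared_screen(G = 6, n_strong = 2, seed = 53)
  expect_error(single_scan_null(scr$dataset, scr$decomp, n_perm = 50),
    class = "influscreen_validation_error"
  )
  n1 <- single_scan_null(scr$dataset, scr$decomp, n_perm = 120, seed = 7)
  n2 <- single_scan_null(scr$dataset, scr$decomp, n_perm = 120, seed = 7)
  expect_identical(n1$max_stats, n2$max_stats)
  expect_gt(n1$evd_params["scale"], 0)
})

test_that("free step-down adjustment matches a brute-force oracle on a tiny case", {
  # independent oracle: literal Westfall-Young free step-down
  oracle <- function(obs, nulls) {
    h <- length(obs)
    ord <- order(abs(obs), decreasing = TRUE)
    q <- abs(nulls[, ord, drop = FALSE])
    adj <- numeric(h)
    for (r in seq_len(h)) {
      succ_max <- apply(q[, r:h, drop = FALSE], 1, max)
      adj[r] <- (sum(succ_max >= abs(obs[ord[r]])) + 1) / (nrow(nulls) + 1)
    }
    adj <- cummax(adj)
    out <- numeric(h)
    out[ord] <- adj
    out
  }
  set.seed(59)
  obs <- c(2.5, 0.4, 1.1)
  nulls <- matrix(rnorm(30), 10, 3)
  expect_equal(stepdown_adjust(obs, nulls), oracle(obs, nulls))

  # a larger random instance
  obs2 <- rnorm(12, sd = 2)
  nulls2 <- matrix(rnorm(25 * 12), 25, 12)
  expect_equal(stepdown_adjust(obs2, nulls2), oracle(obs2, nulls2))
})

test_that("step-down adjustment honours its boundary properties", {
  set.seed(61)
  # one hypothesis: adjusted equals the raw empirical p
  obs <- 1.7
  nulls <- matrix(rnorm(40), 40, 1)
  expect_equal(
    stepdown_adjust(obs, nulls),
    empirical_pvalue(obs, nulls[, 1])
  )
  # identical hypotheses share one adjusted p
  nn <- matrix(rep(rnorm(30), 3), 30, 3)
  adj <- stepdown_adjust(rep(1.2, 3), nn)
  expect_true(all(adj == adj[1]))
  # adjusted values live in (0, 1] and dominate per-column raw p
  obs3 <- rnorm(8)
  nulls3 <- matrix(rnorm(50 * 8), 50, 8)
  adj3 <- stepdown_adjust(obs3, nulls3)
  raw3 <- vapply(1:8, function(j) empirical_pvalue(obs3[j], nulls3[, j]), numeric(1))
  expect_true(all(adj3 > 0 & adj3 <= 1))
  expect_true(all(adj3 >= raw3))
  expect_error(stepdown_adjust(obs3, nulls3[, 1:3]), class = "influscreen_validation_error")
})

test_that("the identity tandem permutation reproduces observed statistics", {
  scr <- prepared_screen(G = 7, n_strong = 3, n_edges = 1, seed = 67)
  X <- scr$dataset$genotype
  n <- nrow(X)
  perms <- matrix(rep(seq_len(n), 2), n, 2)
  res <- influscreen:::pair_engine_cpp(
    U = scr$decomp$U[, 1:2], X = X, L = recomposition_map(scr$decomp),
    covs = list(integer(0), integer(0)),
    pairs = matrix(as.numeric(rbind(c(1, 2), c(3, 5))), ncol = 2),
    perms = matrix(as.numeric(perms), nrow = n),
    cond_limit = 1e8, pole_tol = 1e-8, rcond_tol = 1e-10
  )
  for (p in 1:2) {
    expect_equal(res$null_m[1, 2 * p - 1], abs(res$m[p, 1]) / sqrt(res$var_m[p, 1]))
    expect_equal(res$null_m[2, 2 * p], abs(res$m[p, 2]) / sqrt(res$var_m[p, 2]))
    expect_equal(
      unname(res$null_pheno[1, (p - 1) * 6 + 1:6]),
      unname(abs(res$pheno[p, ]) / res$pheno_se[p, ])
    )
  }
})

test_that("raw influence p-values are uniform on a pure-null screen", {
  scr <- prepared_screen(G = 14, n_strong = 0, seed = 73)
  set.seed(74)
  scan <- single_locus_scan(scr$dataset, scr$decomp)
  null <- single_scan_null(scr$dataset, scr$decomp, n_perm = 120)
  cv <- select_covariates(scan, null)
  pr <- scan_all_pairs(scr$dataset, scr$decomp, cv, n_perm = 150)
  sig <- adjust_significance(pr, pool = FALSE)
  p <- c(sig$influences$p_ab, sig$influences$p_ba)
  p <- p[is.finite(p)]
  expect_gt(length(p), 100)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the per-pair tandem null matches the method's permutation contract", {
  scr <- prepared_screen(G = 8, n_strong = 3, n_edges = 1, seed = 131)
  nul <- tandem_pair_null(scr$dataset, scr$decomp, NULL, "g01", "g03",
    n_perm = 120, seed = 9
  )
  expect_s3_class(nul, "kd_pair_null")
  expect_equal(dim(nul$m_stats), c(120L, 2L))
  expect_true(all(nul$m_stats[is.finite(nul$m_stats)] >= 0))
  expect_true(nul$reliable)
  # empirical p from this null is a valid probability
  p <- empirical_pvalue(nul$observed$stat_ab, nul$m_stats[, "m_ab"])
  expect_gt(p, 0)
  expect_lte(p, 1)
  # reproducible under the same seed
  nul2 <- tandem_pair_null(scr$dataset, scr$decomp, NULL, "g01", "g03",
    n_perm = 120, seed = 9
  )
  expect_identical(nul$m_stats, nul2$m_stats)
})
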